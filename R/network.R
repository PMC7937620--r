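#' Construct a gene network
#'
#' A `gene_network` is one "view" of a gene universe: an undirected,
#' weighted (or binary) graph stored as a symmetric non-negative weight
#' matrix with a zero diagonal. A weight of 0 means "no edge".
#'
#' @param genes Character vector of unique gene identifiers.
#' @param weights Symmetric `n x n` numeric matrix of non-negative edge
#'   weights; the diagonal must be zero.
#' @param name Name of the network view (e.g. `"ppi"`).
#' @param is_binary Logical; if `NULL` (default), detected from the matrix
#'   (`TRUE` when all entries are 0 or 1).
#' @return An object of class `gene_network` with fields `name`, `genes`,
#'   `weights` and `is_binary`.
#' @export
gene_network <- function(genes, weights, name = "network", is_binary = NULL) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  n <- length(genes)
  if (!all(dim(weights) == c(n, n)))
    stop("weight matrix dimension does not match gene list length")
  if (any(weights < 0)) stop("negative edge weights are not allowed")
  if (any(abs(weights - t(weights)) > 1e-12)) stop("weight matrix must be symmetric")
  if (any(diag(weights) != 0)) stop("weight matrix must have a zero diagonal")
  dimnames(weights) <- list(genes, genes)
  if (is.null(is_binary)) is_binary <- all(weights %in% c(0, 1))
  structure(
    list(name = name, genes = genes, weights = weights, is_binary = is_binary),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  n_edges <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf(
    "gene_network '%s': %d genes, %d edges (%s)\n",
    x$name, length(x$genes), n_edges,
    if (x$is_binary) "binary" else "weighted"
  ))
  invisible(x)
}

#' Construct a disease annotation
#'
#' Maps genes to sets of integer disease-class codes in `1..K`. Genes may
#' carry several codes (multi-tag genes); genes absent from `tags` are
#' unannotated (empty tag set). Code 0 is reserved for "no tag" and never
#' appears in a tag set.
#'
#' @param tags Named list; each element an integer vector of class codes
#'   in `1..n_classes` for one gene.
#' @param n_classes Number of disease classes `K`.
#' @param target_class Integer code of the identified target class.
#' @param class_names Optional character vector of length `n_classes`.
#' @return An object of class `disease_annotation`.
#' @export
disease_annotation <- function(tags, n_classes, target_class,
                               class_names = NULL) {
  n_classes <- as.integer(n_classes)
  target_class <- as.integer(target_class)
  if (n_classes < 1) stop("n_classes must be >= 1")
  if (target_class < 1 || target_class > n_classes)
    stop("target_class must lie in 1..n_classes")
  if (is.null(names(tags)) && length(tags) > 0)
    stop("tags must be a named list (gene -> codes)")
  tags <- lapply(tags, function(v) sort(unique(as.integer(v))))
  bad <- vapply(tags, function(v) any(v < 1 | v > n_classes), logical(1))
  if (any(bad))
    stop("class codes must lie in 1..", n_classes,
         " (0 is reserved for 'no tag'); offending gene: ",
         names(tags)[which(bad)[1]])
  if (is.null(class_names)) class_names <- paste0("class", seq_len(n_classes))
  if (length(class_names) != n_classes)
    stop("class_names must have length n_classes")
  structure(
    list(tags = tags, n_classes = n_classes, target_class = target_class,
         class_names = class_names),
    class = "disease_annotation"
  )
}

#' @export
print.disease_annotation <- function(x, ...) {
  n_multi <- sum(lengths(x$tags) > 1)
  cat(sprintf(
    "disease_annotation: %d annotated genes, %d classes, target '%s' (%d multi-tag)\n",
    length(x$tags), x$n_classes, x$class_names[x$target_class], n_multi
  ))
  invisible(x)
}

#' Tag set of a gene
#'
#' @param annotation A `disease_annotation`.
#' @param gene Gene identifier.
#' @return Integer vector of class codes (length 0 if unannotated).
#' @export
gene_tags <- function(annotation, gene) {
  v <- annotation$tags[[gene]]
  if (is.null(v)) integer(0) else v
}

#' Hide the tags of selected genes
#'
#' Returns a copy of the annotation in which `genes` are unannotated.
#' Used by the label-masking protocol: evaluation genes have their own
#' tags hidden during representation so that the centre-tag rule cannot
#' leak the label being predicted.
#'
#' @param annotation A `disease_annotation`.
#' @param genes Character vector of genes to mask.
#' @return A `disease_annotation` with the given genes' tag sets emptied.
#' @export
mask_annotation <- function(annotation, genes) {
  annotation$tags <- annotation$tags[setdiff(names(annotation$tags), genes)]
  annotation
}
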