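#' Read an undirected network from an edge-list file
#'
#' The format is plain text, one edge per line:
#' `gene_a<TAB>gene_b[<TAB>weight]` (any run of spaces/tabs separates
#' fields). Lines starting with `#` and blank lines are skipped. Two-column
#' lines receive `default_weight`. Duplicate edges keep the maximum weight;
#' self-loops are dropped (the gene itself is kept).
#'
#' @param path Path to the edge-list file.
#' @param default_weight Weight assigned to two-column lines (default 1).
#' @param name Network name (defaults to the file name without extension).
#' @return A [gene_network()] over the genes seen in the file, in order of
#'   first appearance.
#' @export
read_edge_list <- function(path, default_weight = 1, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  ga <- gb <- character(length(idx)); w <- numeric(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (!(length(f) %in% c(2L, 3L)))
      stop(sprintf("parse error at line %d: expected 2 or 3 fields, got %d",
                   i, length(f)))
    wt <- if (length(f) == 3L) suppressWarnings(as.numeric(f[3])) else default_weight
    if (is.na(wt))
      stop(sprintf("parse error at line %d: weight '%s' is not numeric", i, f[3]))
    if (wt < 0)
      stop(sprintf("validation error at line %d: negative weight %g", i, wt))
    ga[j] <- f[1]; gb[j] <- f[2]; w[j] <- wt
  }
  genes <- unique(c(rbind(ga, gb)))
  n <- length(genes)
  W <- matrix(0, n, n, dimnames = list(genes, genes))
  for (j in seq_along(ga)) {
    if (ga[j] == gb[j]) next  # self-loops dropped
    cur <- W[ga[j], gb[j]]
    W[ga[j], gb[j]] <- W[gb[j], ga[j]] <- max(cur, w[j])
  }
  gene_network(genes, W, name = name)
}

#' Write a network as an edge-list file
#'
#' Writes the upper triangle of the weight matrix, one nonzero edge per
#' line; binary networks are written without the weight column. Reading
#' the file back with [read_edge_list()] reproduces the weight matrix.
#'
#' @param network A [gene_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  W <- network$weights
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  a <- network$genes[ut[, 1]]; b <- network$genes[ut[, 2]]
  lines <- if (network$is_binary) {
    paste(a, b, sep = "\t")
  } else {
    paste(a, b, sprintf("%.17g", W[ut]), sep = "\t")
  }
  # isolated genes still need to appear so the gene set round-trips
  iso <- setdiff(network$genes, unique(c(a, b)))
  lines <- c(lines, if (length(iso)) paste(iso, iso, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene-disease annotations
#'
#' Format: `gene<TAB>code[,code...]`, one gene per line; `#` comments and
#' blank lines skipped. Codes are integers in `1..n_classes`; 0 is
#' rejected (reserved for "no tag"). Genes absent from the file are
#' unannotated. Repeated genes accumulate the union of their codes.
#'
#' @param path Path to the annotation file.
#' @param n_classes Number of disease classes `K`.
#' @param target_class Code of the identified target class.
#' @param class_names Optional class names, length `n_classes`.
#' @return A [disease_annotation()].
#' @export
read_annotations <- function(path, n_classes, target_class,
                             class_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  tags <- list()
  for (i in keep) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 2L)
      stop(sprintf("parse error at line %d: expected 'gene<TAB>codes'", i))
    codes <- suppressWarnings(as.integer(strsplit(f[2], ",")[[1]]))
    if (anyNA(codes))
      stop(sprintf("parse error at line %d: non-integer class code", i))
    if (any(codes < 1 | codes > n_classes))
      stop(sprintf(
        "validation error at line %d: class code outside 1..%d (0 is reserved)",
        i, n_classes))
    tags[[f[1]]] <- sort(unique(c(tags[[f[1]]], codes)))
  }
  disease_annotation(tags, n_classes, target_class, class_names)
}

#' Write gene-disease annotations
#'
#' @param annotation A [disease_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotation, path) {
  lines <- vapply(names(annotation$tags), function(g) {
    paste(g, paste(annotation$tags[[g]], collapse = ","), sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Harmonize gene universes across network views
#'
#' Restricts a list of network views to the genes present in at least
#' `min_presence` of them and puts every output on one shared gene
#' ordering (order of first appearance while scanning the views). A gene
#' missing from a particular view gets an all-zero (isolated) row/column
#' there, so matrix indices align across views for fusion.
#'
#' @param networks List of [gene_network()] views.
#' @param min_presence Minimum number of views a gene must appear in.
#' @return List of `gene_network`s over the shared gene ordering.
#' @export
harmonize <- function(networks, min_presence = length(networks)) {
  if (length(networks) < 1) stop("need at least one network")
  if (min_presence > length(networks))
    stop("min_presence exceeds the number of networks")
  all_genes <- unique(unlist(lapply(networks, `[[`, "genes")))
  presence <- Reduce(`+`, lapply(networks, function(nw) all_genes %in% nw$genes))
  kept <- all_genes[presence >= min_presence]
  if (length(kept) == 0)
    stop("no gene is present in at least ", min_presence, " views")
  lapply(networks, function(nw) {
    W <- matrix(0, length(kept), length(kept), dimnames = list(kept, kept))
    common <- intersect(kept, nw$genes)
    W[common, common] <- nw$weights[common, common]
    gene_network(kept, W, name = nw$name, is_binary = nw$is_binary)
  })
}
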