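#' Serialize a representation dataset to plain text
#'
#' Writes `images.tsv` (one row per gene, the row-major flattened image),
#' `t_center.tsv` (gene, resolved centre tag) and `params.json` (m, k,
#' cap, style, target class, network name) into `dir`.
#'
#' @param dataset A [represent_all()] / [fuse_networks()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_representation_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- flatten_stack(dataset$images)
  utils::write.table(
    data.frame(gene = dataset$genes, X, check.names = FALSE),
    file.path(dir, "images.tsv"), sep = "\t", row.names = FALSE,
    col.names = FALSE, quote = FALSE
  )
  utils::write.table(
    data.frame(gene = dataset$genes, t_center = dataset$t_center),
    file.path(dir, "t_center.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  jsonlite::write_json(dataset$params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a representation dataset written by [write_representation_dataset()]
#'
#' @param dir Directory holding `images.tsv`, `t_center.tsv`, `params.json`.
#' @return A `representation_dataset`.
#' @export
read_representation_dataset <- function(dir) {
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE)
  m <- params$m
  tab <- utils::read.table(file.path(dir, "images.tsv"), sep = "\t",
                           colClasses = c("character", rep("numeric", m * m)))
  tc <- utils::read.table(file.path(dir, "t_center.tsv"), sep = "\t",
                          header = TRUE, colClasses = c("character", "integer"))
  genes <- tab[[1]]
  images <- array(0, c(length(genes), m, m), dimnames = list(genes, NULL, NULL))
  for (i in seq_along(genes))
    images[i, , ] <- matrix(as.numeric(tab[i, -1]), m, m, byrow = TRUE)
  structure(
    list(images = images, genes = genes,
         t_center = tc$t_center[match(genes, tc$gene)], params = params),
    class = "representation_dataset"
  )
}
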