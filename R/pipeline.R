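#' End-to-end target-class gene classification with label masking
#'
#' Runs the complete experiment on one or several network views: select a
#' balanced positive/negative gene panel, hold out a stratified test
#' split, mask the held-out genes' tags (so the representation cannot see
#' the labels it is asked to predict), build the image-like
#' representations, train the requested classifier and evaluate it on the
#' held-out genes.
#'
#' @param networks A [gene_network()] or list of them (harmonized). With
#'   several views the fused representation ([fuse_networks()]) is used.
#' @param annotation A [disease_annotation()] (unmasked).
#' @param kind Classifier kind, see [train_classifier()].
#' @param m,k,cap Representation parameters, see [represent_all()].
#' @param style `"environment"` (default) or `"baseline"`
#'   (no-environment ablation; single view only).
#' @param reference Reference view index for fusion (default 1).
#' @param test_fraction Held-out fraction.
#' @param seed Integer seed (panel sampling, split, training).
#' @param shuffle_labels Permute the panel's labels before splitting —
#'   the null control; any real signal is destroyed.
#' @param ... Passed to [train_classifier()].
#' @return List with `report` (an [evaluate_scores()] result), `auc`,
#'   `classifier`, and `genes` (the balanced panel).
#' @export
run_experiment <- function(networks, annotation, kind = "cnn", m = 21,
                           k = NULL, cap = 1e12,
                           style = c("environment", "baseline"),
                           reference = 1, test_fraction = 0.2, seed = 1,
                           shuffle_labels = FALSE, ...) {
  style <- match.arg(style)
  if (inherits(networks, "gene_network")) networks <- list(networks)
  genes_universe <- networks[[reference]]$genes

  labels_all <- planted_truth(annotation, genes_universe)
  annotated <- lengths(lapply(genes_universe, gene_tags,
                              annotation = annotation)) > 0
  pos <- genes_universe[labels_all == 1]
  neg_pool <- genes_universe[annotated & labels_all == 0]
  if (length(neg_pool) < length(pos))
    stop("fewer eligible negatives than positives")
  neg <- with_seed(seed, sample(neg_pool, length(pos)))
  panel <- c(pos, neg)
  labels <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  if (shuffle_labels)
    labels <- with_seed(seed + 7L, sample(labels))

  test_idx <- stratified_split(labels, test_fraction, seed)
  masked <- mask_annotation(annotation, panel[test_idx])

  ds <- if (length(networks) > 1) {
    fuse_networks(networks, reference, masked, k = k, m = m, genes = panel,
                  cap = cap)
  } else {
    represent_all(networks[[1]], masked, k = k, m = m, genes = panel,
                  cap = cap, style = style)
  }
  data <- structure(
    list(images = ds$images, labels = labels, genes = panel),
    class = "labeled_dataset"
  )
  clf <- train_classifier(kind, data, seed = seed, test_idx = test_idx, ...)
  report <- evaluate_scores(clf$scores, clf$labels)
  list(report = report, auc = report$auc, classifier = clf, genes = panel)
}
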