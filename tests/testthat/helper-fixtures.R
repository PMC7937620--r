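# Fixtures are built in code: no data files.

# Small deterministic weighted network from explicit edges.
edge_network <- function(edges, genes = NULL, name = "toy") {
  if (is.null(genes)) genes <- unique(c(t(as.matrix(edges[, 1:2]))))
  W <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  for (i in seq_len(nrow(edges))) {
    W[edges[i, 1], edges[i, 2]] <- W[edges[i, 2], edges[i, 1]] <-
      as.numeric(edges[i, 3])
  }
  gene_network(genes, W, name = name)
}

# Seeded Erdos-Renyi-ish weighted network.
random_network <- function(n, p = 0.3, seed = 1, weighted = TRUE) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < p]
  W[on] <- if (weighted) runif(length(on), 0.2, 2) else 1
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  gene_network(paste0("g", seq_len(n)), W, name = paste0("rand", seed))
}

# Hand-built similarity + leaf order for selection tests.
manual_similarity <- function(S, cap = 1e12) {
  structure(list(S = S, cap = cap, use_sqrt = FALSE),
            class = "similarity_matrix")
}

manual_order <- function(ord) {
  pos <- integer(length(ord)); pos[ord] <- seq_along(ord)
  structure(list(order = ord, position = pos), class = "leaf_order")
}

# Balanced image dataset with a planted diagonal signal: positives carry
# a low class value, negatives a high one, plus noise.
planted_images <- function(n_per_class = 30, m = 9, seed = 1, strength = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  images <- array(rnorm(n * m * m, 0, 0.3)^2, c(n, m, m))
  labels <- rep(c(1L, 0L), each = n_per_class)
  for (i in seq_len(n)) {
    d <- if (labels[i] == 1) 0.25 else 1.25
    images[i, , ][cbind(2:m, 2:m)] <- d * strength + rnorm(m - 1, 0, 0.1)
  }
  structure(list(images = images, labels = labels,
                 genes = paste0("s", seq_len(n))),
            class = "labeled_dataset")
}
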