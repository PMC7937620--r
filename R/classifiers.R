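#' Assemble a balanced labelled dataset
#'
#' Positives are all genes in the representation dataset that the
#' annotation tags with the target class; negatives are an equal-count
#' sample, drawn uniformly (seeded) from the genes annotated with other
#' classes only. Multi-tag genes carrying the target class are positives
#' and never enter the negative pool. Unannotated genes are excluded.
#'
#' @param dataset A [represent_all()] / [fuse_networks()] result.
#' @param annotation The original (unmasked) [disease_annotation()].
#' @param seed Integer seed for the negative sample.
#' @return An object of class `labeled_dataset`: `images` (N x m x m
#'   array), `labels` (0/1), `genes`.
#' @export
assemble_dataset <- function(dataset, annotation, seed = 1) {
  labels_all <- planted_truth(annotation, dataset$genes)
  annotated <- lengths(lapply(dataset$genes, gene_tags,
                              annotation = annotation)) > 0
  pos <- dataset$genes[labels_all == 1]
  neg_pool <- dataset$genes[annotated & labels_all == 0]
  if (length(pos) == 0) stop("no positive genes in the dataset")
  if (length(neg_pool) < length(pos))
    stop("fewer eligible negatives (", length(neg_pool),
         ") than positives (", length(pos), ")")
  neg <- with_seed(seed, sample(neg_pool, length(pos)))
  genes <- c(pos, neg)
  idx <- match(genes, dataset$genes)
  structure(
    list(images = dataset$images[idx, , , drop = FALSE],
         labels = c(rep(1L, length(pos)), rep(0L, length(neg))),
         genes = genes),
    class = "labeled_dataset"
  )
}

#' Flatten an image to a feature vector
#'
#' Row-major flattening of an `m x m` image: a 21x21 image becomes a
#' 441-dimensional vector, the input format of the classical learners.
#'
#' @param image An `m x m` matrix or a `representation_image`.
#' @return Numeric vector of length `m * m`.
#' @export
flatten <- function(image) {
  if (inherits(image, "representation_image")) image <- image$E
  as.vector(t(image))
}

# N x (m*m) design matrix from an image stack (row-major per image).
flatten_stack <- function(images) {
  t(apply(images, 1, function(M) as.vector(t(M))))
}

#' Stratified train/test split
#'
#' @param labels 0/1 labels.
#' @param test_fraction Fraction held out per class.
#' @param seed Integer seed.
#' @return Integer vector of test indices.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1) {
  with_seed(seed, {
    idx <- unlist(lapply(unique(labels), function(cl) {
      members <- which(labels == cl)
      sample(members, max(1, round(test_fraction * length(members))))
    }))
    sort(idx)
  })
}

#' Train a classifier on labelled representation images
#'
#' Dispatches to one of six learners. The CNN consumes the raw `m x m`
#' images; the five classical learners consume row-major flattened
#' vectors, standardized feature-wise on the training split (the image
#' mixes edge weights with class values, which hurts kernel methods at
#' raw scale). Scores are probabilities in `[0, 1]`.
#'
#' @param kind One of `"cnn"`, `"svm_gaussian"`, `"svm_polynomial"`,
#'   `"decision_tree"`, `"extra_trees"`, `"naive_bayes"`.
#' @param data A [assemble_dataset()] result.
#' @param test_fraction Held-out fraction (stratified); ignored when
#'   `test_idx` is given.
#' @param seed Integer seed controlling the split and any training
#'   randomness; a fixed seed gives identical scores across runs.
#' @param test_idx Optional explicit test indices (used by the masking
#'   protocol, where the held-out genes are fixed before representation).
#' @param ... Passed to the underlying fitter (e.g. `epochs` for the CNN).
#' @return An object of class `net_classifier` with `kind`, `model`,
#'   `scores` (held-out scores), `labels`, `genes` (held-out) and `seed`.
#' @export
train_classifier <- function(kind = c("cnn", "svm_gaussian", "svm_polynomial",
                                      "decision_tree", "extra_trees",
                                      "naive_bayes"),
                             data, test_fraction = 0.2, seed = 1,
                             test_idx = NULL, ...) {
  kind <- match.arg(kind)
  y <- data$labels
  if (is.null(test_idx)) test_idx <- stratified_split(y, test_fraction, seed)
  train_idx <- setdiff(seq_along(y), test_idx)
  if (length(unique(y[train_idx])) < 2 || length(unique(y[test_idx])) < 2)
    stop("a class is missing from the train or test split")

  if (kind == "cnn") {
    model <- fit_cnn(data$images[train_idx, , , drop = FALSE], y[train_idx],
                     seed = seed, ...)
    scores <- predict_cnn(model, data$images[test_idx, , , drop = FALSE])
  } else {
    X <- flatten_stack(data$images)
    mu <- colMeans(X[train_idx, , drop = FALSE])
    sd <- apply(X[train_idx, , drop = FALSE], 2, stats::sd)
    sd[sd == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
    Xtr <- Xs[train_idx, , drop = FALSE]; Xte <- Xs[test_idx, , drop = FALSE]
    ytr <- y[train_idx]
    model <- switch(kind,
      svm_gaussian = fit_svm(Xtr, ytr, kernel = "gaussian", seed = seed, ...),
      svm_polynomial = fit_svm(Xtr, ytr, kernel = "polynomial", seed = seed, ...),
      decision_tree = fit_tree(Xtr, ytr, ...),
      extra_trees = fit_extra_trees(Xtr, ytr, seed = seed, ...),
      naive_bayes = fit_naive_bayes(Xtr, ytr)
    )
    model$center <- mu; model$scale <- sd
    scores <- predict_flat(model, Xte)
  }
  structure(
    list(kind = kind, model = model, scores = unname(scores),
         labels = y[test_idx], genes = data$genes[test_idx],
         test_idx = test_idx, seed = seed),
    class = "net_classifier"
  )
}

#' @export
print.net_classifier <- function(x, ...) {
  cat(sprintf("net_classifier '%s': %d held-out samples, seed %d\n",
              x$kind, length(x$scores), x$seed))
  invisible(x)
}

#' Score new samples with a trained classifier
#'
#' @param object A [train_classifier()] result.
#' @param images An `N x m x m` image array (or a single `m x m` matrix).
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict.net_classifier <- function(object, images, ...) {
  if (is.matrix(images)) images <- array(images, c(1, dim(images)))
  if (object$kind == "cnn") return(predict_cnn(object$model, images))
  X <- flatten_stack(images)
  Xs <- sweep(sweep(X, 2, object$model$center), 2, object$model$scale, "/")
  predict_flat(object$model, Xs)
}

predict_flat <- function(model, X) {
  switch(model$fit,
    svm = predict_svm(model, X),
    tree = vapply(seq_len(nrow(X)), function(i) tree_score(model$tree, X[i, ]),
                  numeric(1)),
    extra_trees = {
      p <- vapply(model$trees, function(tr)
        vapply(seq_len(nrow(X)), function(i) tree_score(tr, X[i, ]),
               numeric(1)), numeric(nrow(X)))
      if (is.null(dim(p))) mean(p) else rowMeans(p)
    },
    naive_bayes = predict_nb(model, X)
  )
}

#' Write held-out scores as a TSV table
#'
#' @param classifier A [train_classifier()] result.
#' @param path Output path for `gene<TAB>label<TAB>score`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(classifier, path) {
  utils::write.table(
    data.frame(gene = classifier$genes, label = classifier$labels,
               score = classifier$scores),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

## ---- Gaussian naive Bayes ----

fit_naive_bayes <- function(X, y) {
  stats <- lapply(c(0, 1), function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    list(mean = colMeans(Xc),
         var = pmax(apply(Xc, 2, stats::var), 1e-9),
         prior = mean(y == cl))
  })
  list(fit = "naive_bayes", classes = stats)
}

predict_nb <- function(model, X) {
  loglik <- function(s) {
    rowSums(sweep(-(sweep(X, 2, s$mean))^2, 2, 2 * s$var, "/")) -
      sum(log(s$var)) / 2 + log(s$prior)
  }
  l0 <- loglik(model$classes[[1]]); l1 <- loglik(model$classes[[2]])
  1 / (1 + exp(pmin(700, pmax(-700, l0 - l1))))
}

## ---- CART decision tree & extremely randomized trees ----

# Best axis-aligned split by Gini impurity over the given features.
# random_threshold = TRUE draws one uniform threshold per feature
# (extra-trees style) instead of scanning all midpoints.
best_split <- function(X, y, features, random_threshold = FALSE) {
  n <- length(y)
  parent <- 1 - mean(y)^2 - (1 - mean(y))^2
  best <- list(gain = 1e-12)
  for (f in features) {
    x <- X[, f]
    if (random_threshold) {
      r <- range(x)
      if (r[1] == r[2]) next
      thr <- stats::runif(1, r[1], r[2])
      cand <- thr
    } else {
      u <- sort(unique(x))
      if (length(u) < 2) next
      cand <- (utils::head(u, -1) + utils::tail(u, -1)) / 2
    }
    for (thr in cand) {
      left <- x <= thr
      nl <- sum(left); nr <- n - nl
      if (nl == 0 || nr == 0) next
      pl <- mean(y[left]); pr <- mean(y[!left])
      gini <- nl / n * (1 - pl^2 - (1 - pl)^2) +
              nr / n * (1 - pr^2 - (1 - pr)^2)
      gain <- parent - gini
      if (gain > best$gain + 1e-12) best <- list(gain = gain, f = f, thr = thr)
    }
  }
  if (is.null(best$f)) NULL else best
}

grow_tree <- function(X, y, depth, max_depth, min_split, mtry = NULL,
                      random_threshold = FALSE) {
  if (depth >= max_depth || length(y) < min_split || length(unique(y)) == 1)
    return(list(leaf = TRUE, p = mean(y)))
  features <- if (is.null(mtry)) seq_len(ncol(X))
              else sample(ncol(X), min(mtry, ncol(X)))
  sp <- best_split(X, y, features, random_threshold)
  if (is.null(sp)) return(list(leaf = TRUE, p = mean(y)))
  left <- X[, sp$f] <= sp$thr
  list(leaf = FALSE, f = sp$f, thr = sp$thr,
       left = grow_tree(X[left, , drop = FALSE], y[left], depth + 1,
                        max_depth, min_split, mtry, random_threshold),
       right = grow_tree(X[!left, , drop = FALSE], y[!left], depth + 1,
                         max_depth, min_split, mtry, random_threshold))
}

tree_score <- function(node, x) {
  while (!node$leaf) node <- if (x[node$f] <= node$thr) node$left else node$right
  node$p
}

fit_tree <- function(X, y, max_depth = 20, min_split = 2) {
  list(fit = "tree",
       tree = grow_tree(X, y, 0, max_depth, min_split))
}

fit_extra_trees <- function(X, y, n_trees = 100, max_depth = 15,
                            min_split = 2, seed = 1) {
  mtry <- max(1, floor(sqrt(ncol(X))))
  trees <- with_seed(seed + 211L, lapply(seq_len(n_trees), function(b)
    grow_tree(X, y, 0, max_depth, min_split, mtry = mtry,
              random_threshold = TRUE)))
  list(fit = "extra_trees", trees = trees)
}

## ---- kernel SVM (simplified SMO) with Platt-scaled scores ----

kernel_matrix <- function(X1, X2, kernel, par) {
  if (kernel == "gaussian") {
    d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * X1 %*% t(X2)
    exp(-par$gamma * pmax(d2, 0))
  } else {
    (par$gamma * X1 %*% t(X2) + 1)^par$degree
  }
}

fit_svm <- function(X, y, kernel = c("gaussian", "polynomial"), C = 1,
                    seed = 1, tol = 1e-3, max_passes = 5, max_sweeps = 200) {
  kernel <- match.arg(kernel)
  n <- nrow(X)
  par <- if (kernel == "gaussian") {
    d2 <- as.vector(stats::dist(X))^2
    med <- stats::median(d2[d2 > 0])
    list(gamma = 1 / (2 * ifelse(is.finite(med) && med > 0, med, 1)))
  } else {
    list(gamma = 1 / ncol(X), degree = 3)
  }
  K <- kernel_matrix(X, X, kernel, par)
  ys <- 2 * y - 1
  alpha <- numeric(n); b <- 0
  with_seed(seed + 97L, {
    passes <- 0; sweeps <- 0
    while (passes < max_passes && sweeps < max_sweeps) {
      changed <- 0
      for (i in seq_len(n)) {
        Ei <- sum(alpha * ys * K[, i]) + b - ys[i]
        if ((ys[i] * Ei < -tol && alpha[i] < C) ||
            (ys[i] * Ei > tol && alpha[i] > 0)) {
          j <- sample(setdiff(seq_len(n), i), 1)
          Ej <- sum(alpha * ys * K[, j]) + b - ys[j]
          ai_old <- alpha[i]; aj_old <- alpha[j]
          if (ys[i] != ys[j]) {
            L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
          } else {
            L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
          }
          if (L >= H) next
          eta <- 2 * K[i, j] - K[i, i] - K[j, j]
          if (eta >= 0) next
          aj <- min(H, max(L, aj_old - ys[j] * (Ei - Ej) / eta))
          if (abs(aj - aj_old) < 1e-5) next
          ai <- ai_old + ys[i] * ys[j] * (aj_old - aj)
          alpha[i] <- ai; alpha[j] <- aj
          b1 <- b - Ei - ys[i] * (ai - ai_old) * K[i, i] -
            ys[j] * (aj - aj_old) * K[i, j]
          b2 <- b - Ej - ys[i] * (ai - ai_old) * K[i, j] -
            ys[j] * (aj - aj_old) * K[j, j]
          b <- if (ai > 0 && ai < C) b1
               else if (aj > 0 && aj < C) b2
               else (b1 + b2) / 2
          changed <- changed + 1
        }
      }
      passes <- if (changed == 0) passes + 1 else 0
      sweeps <- sweeps + 1
    }
  })
  f_train <- as.vector(K %*% (alpha * ys)) + b
  platt <- tryCatch(
    stats::coef(suppressWarnings(
      stats::glm(y ~ f_train, family = stats::binomial()))),
    error = function(e) c(0, 1)
  )
  if (anyNA(platt)) platt <- c(0, 1)
  list(fit = "svm", kernel = kernel, par = par, X = X,
       coef = alpha * ys, b = b, platt = platt)
}

predict_svm <- function(model, Xnew) {
  f <- as.vector(kernel_matrix(Xnew, model$X, model$kernel, model$par) %*%
                   model$coef) + model$b
  stats::plogis(model$platt[1] + model$platt[2] * f)
}
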