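#' Configuration for the synthetic network generator
#'
#' Describes a degree-corrected planted-partition world: `n` genes split
#' into `K` class regions, expected degrees drawn from a power law with
#' exponent `gamma` (the scale-free signature of protein interaction
#' networks), a fraction `mu` of each gene's connectivity leaving its own
#' region, partial annotation with multi-tag genes, and optionally several
#' correlated views of the same gene set for fusion experiments.
#'
#' @param n Number of genes.
#' @param gamma Degree-distribution exponent (density tail `k^-gamma`).
#' @param K Number of disease classes / planted regions.
#' @param mu Mixing parameter in `[0, 1]`: fraction of a gene's expected
#'   edge mass that crosses region boundaries.
#' @param mean_degree Target mean expected degree (default 20, the order
#'   of magnitude of curated protein-interaction networks once restricted
#'   to a well-covered gene universe; sets the Pareto minimum). Requires
#'   `gamma > 2`; for heavier tails the minimum expected degree is fixed
#'   at 2 instead.
#' @param annotated_frac Fraction of genes carrying at least one tag.
#' @param multitag_prob Probability an annotated gene also carries the
#'   class of an adjacent region.
#' @param n_views Number of network views to emit.
#' @param view_noise Perturbation scale of the extra views: multiplicative
#'   weight jitter and the fraction of edges rewired.
#' @param binarize_last Emit the last extra view as a binary network.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n = 800, gamma = 2.5, K = 8, mu = 0.2,
                             annotated_frac = 0.3, multitag_prob = 0.2,
                             mean_degree = 20, n_views = 1, view_noise = 0.3,
                             binarize_last = FALSE, seed = 1) {
  stopifnot(n > K, K >= 2, mu >= 0, mu <= 1,
            annotated_frac >= 0, annotated_frac <= 1,
            multitag_prob >= 0, multitag_prob <= 1,
            n_views >= 1, view_noise >= 0, gamma > 1, mean_degree > 0)
  structure(
    list(n = as.integer(n), gamma = gamma, K = as.integer(K), mu = mu,
         annotated_frac = annotated_frac, multitag_prob = multitag_prob,
         mean_degree = mean_degree,
         n_views = as.integer(n_views), view_noise = view_noise,
         binarize_last = binarize_last, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Run code with a local, restorable RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  code
}

#' Generate synthetic networks with planted disease-class structure
#'
#' Builds a degree-corrected planted-partition graph: genes are split
#' evenly into `K` regions; expected degrees follow a Pareto law with
#' density exponent `gamma` (minimum 2, capped so edge probabilities stay
#' valid); an edge between genes `i, j` appears with probability
#' `theta_i * theta_j / sum(theta)` times `(1 - mu) K` within a region or
#' `mu K / (K - 1)` across regions, so expected degrees are preserved and
#' a fraction `mu` of edges cross regions. Edge weights are uniform on
#' `[0.5, 1.5]`. A fraction `annotated_frac` of genes is tagged with its
#' region's class; with probability `multitag_prob` an annotated gene also
#' gains the class of the adjacent region it is most strongly wired to.
#' Additional views keep the gene set, jitter kept-edge weights by a
#' `1 + N(0, view_noise)` factor and rewire a `view_noise` fraction of
#' edges to random non-adjacent pairs.
#'
#' @param config A [synthetic_config()].
#' @return List with `networks` (list of [gene_network()]s, the base view
#'   first), `annotation` (a [disease_annotation()], target class 1) and
#'   `regions` (named integer vector of planted regions).
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n; K <- config$K; mu <- config$mu
    genes <- sprintf("g%04d", seq_len(n))
    region <- sample(rep(seq_len(K), length.out = n))
    names(region) <- genes

    # Pareto expected degrees: density ~ theta^-gamma, so CCDF ~ theta^-(gamma-1);
    # the minimum is set so the mean expected degree hits config$mean_degree
    tmin <- if (config$gamma > 2) {
      config$mean_degree * (config$gamma - 2) / (config$gamma - 1)
    } else 2
    theta <- tmin * (1 - stats::runif(n))^(-1 / (config$gamma - 1))
    theta <- pmin(theta, sqrt(sum(theta)))  # keep p_ij <= 1 in the tail
    if (sum(theta) <= 0) stop("infeasible degree sequence")

    B_in <- (1 - mu) * K
    B_out <- if (K > 1) mu * K / (K - 1) else 0
    same <- outer(region, region, `==`)
    P <- outer(theta, theta) / sum(theta) * ifelse(same, B_in, B_out)
    P <- pmin(P, 1); diag(P) <- 0
    U <- matrix(stats::runif(n * n), n, n)
    U[lower.tri(U, diag = TRUE)] <- t(U)[lower.tri(U, diag = TRUE)]
    edge <- U < P
    Wgt <- matrix(stats::runif(n * n, 0.5, 1.5), n, n)
    Wgt[lower.tri(Wgt, diag = TRUE)] <- t(Wgt)[lower.tri(Wgt, diag = TRUE)]
    # realized weight carries the region propensity: within-region edges
    # are (1 - mu)-strong, cross-region edges mu-strong
    propensity <- ifelse(same, 1 - mu, mu)
    W <- ifelse(edge, propensity * Wgt, 0)
    diag(W) <- 0
    base <- gene_network(genes, W, name = "view1", is_binary = FALSE)

    # annotations: region class, plus a neighbouring region's class for
    # a multitag_prob share of annotated genes
    annotated <- sort(sample(n, round(config$annotated_frac * n)))
    tags <- list()
    for (i in annotated) {
      tg <- region[i]
      if (stats::runif(1) < config$multitag_prob) {
        out_w <- tapply(W[i, ], region, sum)
        out_w[tg] <- -Inf
        second <- as.integer(names(out_w)[which.max(out_w)])
        if (is.finite(max(out_w)) && max(out_w) > 0) tg <- c(tg, second)
        else tg <- c(tg, sample(setdiff(seq_len(K), tg), 1))
      }
      tags[[genes[i]]] <- tg
    }
    annotation <- disease_annotation(tags, n_classes = K, target_class = 1)

    networks <- list(base)
    if (config$n_views > 1) {
      for (v in 2:config$n_views) {
        Wv <- perturb_view(W, config$view_noise)
        binar <- config$binarize_last && v == config$n_views
        if (binar) Wv <- (Wv > 0) * 1
        networks[[v]] <- gene_network(genes, Wv, name = paste0("view", v),
                                      is_binary = binar)
      }
    }
    list(networks = networks, annotation = annotation, regions = region)
  })
}

# Jitter weights and rewire a `noise` fraction of edges; keeps symmetry.
perturb_view <- function(W, noise) {
  n <- nrow(W)
  Wv <- W
  ut <- which(upper.tri(W) & W > 0)
  jit <- pmax(0.1, 1 + stats::rnorm(length(ut), 0, noise))
  Wv[ut] <- Wv[ut] * jit
  n_rewire <- round(noise * length(ut))
  if (n_rewire > 0) {
    drop <- sample(ut, n_rewire)
    Wv[drop] <- 0
    empty <- which(upper.tri(W) & W == 0)
    add <- sample(empty, min(n_rewire, length(empty)))
    Wv[add] <- stats::runif(length(add), 0.5, 1.5)
  }
  Wv[lower.tri(Wv)] <- t(Wv)[lower.tri(Wv)]
  Wv
}

#' Ground-truth binary labels for the target class
#'
#' Returns, for each requested gene, whether the (unmasked) annotation
#' tags it with the target class. Use together with [mask_annotation()]:
#' evaluation genes are masked during representation but keep their
#' ground-truth label here.
#'
#' @param annotation A [disease_annotation()] (the original, unmasked one).
#' @param genes Genes to label (default: all annotated genes).
#' @return Named integer vector of 0/1 labels.
#' @export
planted_truth <- function(annotation, genes = names(annotation$tags)) {
  labels <- vapply(genes, function(g)
    as.integer(annotation$target_class %in% gene_tags(annotation, g)),
    integer(1))
  names(labels) <- genes
  labels
}
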