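#' Pairwise vertex similarity from adjacency rows
#'
#' Each vertex is represented by its row of the weight matrix. The
#' similarity between two vertices is the reciprocal of the sum of squared
#' differences of their rows,
#' \deqn{S_{ij} = 1 / \sum_k (a_{ik} - a_{jk})^2,}
#' so vertices that influence the rest of the network in the same way are
#' highly similar. Identical rows have infinite similarity and are capped
#' at `cap`. Setting `use_sqrt = TRUE` divides by the Euclidean (square
#' root) distance instead; the two readings are monotone-equivalent for
#' neighbour ranking.
#'
#' @param network A [gene_network()] with at least 2 genes.
#' @param cap Similarity assigned to identical rows (default `1e12`).
#' @param use_sqrt Use `1/sqrt(sum of squares)` instead of the reciprocal
#'   of the sum itself. Default `FALSE`.
#' @return An object of class `similarity_matrix`: fields `S` (symmetric
#'   `n x n`, positive off-diagonal), `cap`, `use_sqrt`.
#' @export
compute_similarity <- function(network, cap = 1e12, use_sqrt = FALSE) {
  n <- length(network$genes)
  if (n < 2) stop("similarity needs at least 2 genes")
  d2 <- as.matrix(stats::dist(network$weights))^2
  denom <- if (use_sqrt) sqrt(d2) else d2
  S <- ifelse(denom > 0, 1 / denom, cap)
  dimnames(S) <- list(network$genes, network$genes)
  structure(list(S = S, cap = cap, use_sqrt = use_sqrt),
            class = "similarity_matrix")
}

#' Leaf order of an agglomerative clustering of the vertices
#'
#' Clusters vertices with average-linkage agglomerative hierarchical
#' clustering on the distance `1/S` (the squared-difference sum of
#' adjacency rows, consistent with [compute_similarity()]) and returns the
#' left-to-right sequence of dendrogram leaves. Similar vertices end up
#' close together in this sequence, which is what makes a small window on
#' it a sensible receptive field.
#'
#' @param similarity A `similarity_matrix` from [compute_similarity()].
#' @return An object of class `leaf_order`: `order` (vertex index at each
#'   leaf position) and `position` (leaf position of each vertex), mutually
#'   inverse permutations.
#' @export
leaf_order <- function(similarity) {
  d <- 1 / similarity$S
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ord <- hc$order
  pos <- integer(length(ord))
  pos[ord] <- seq_along(ord)
  structure(list(order = ord, position = pos), class = "leaf_order")
}

#' Select a vertex's neighbourhood inside its receptive field
#'
#' The receptive field of a centre vertex is the `2k+1` window around its
#' position in the leaf order. At a sequence end the truncated side is
#' compensated on the opposite side so the candidate pool always holds
#' `min(2k, n-1)` vertices. Within the pool the `m-1` vertices maximizing
#' the summed similarity to the centre are selected (equivalently: the
#' `m-1` individually most similar candidates); ties go to the smaller
#' leaf position. Members are reported in leaf-sequence order.
#'
#' @param center Vertex index (into `network$genes`).
#' @param order A [leaf_order()].
#' @param similarity A [compute_similarity()] result.
#' @param k Receptive-field radius, `m < k < n`.
#' @param m Image side length (so `m - 1` neighbours are chosen), `m >= 2`.
#' @return An object of class `neighborhood_field`: `center`, `radius`,
#'   `members` (vertex indices in leaf-sequence order), `m`.
#' @export
select_neighborhood <- function(center, order, similarity, k, m) {
  n <- length(order$order)
  if (m < 2) stop("m must be >= 2")
  if (!(m < k && k < n)) stop("need m < k < n")
  p <- order$position[center]
  lo <- p - k; hi <- p + k
  if (lo < 1) { hi <- min(n, hi + (1 - lo)); lo <- 1 }
  if (hi > n) { lo <- max(1, lo - (hi - n)); hi <- n }
  cand_pos <- setdiff(lo:hi, p)
  if (length(cand_pos) < m - 1)
    stop("candidate pool smaller than m - 1")
  sims <- similarity$S[center, order$order[cand_pos]]
  sel <- cand_pos[order(-sims, cand_pos)][seq_len(m - 1)]
  sel <- sort(sel)  # leaf-sequence order
  structure(
    list(center = center, radius = k, members = order$order[sel], m = m),
    class = "neighborhood_field"
  )
}

#' Sub-adjacency matrix of a node-induced sub-network
#'
#' Row/column 1 is the centre vertex; rows/columns `2..m` are the field
#' members in leaf-sequence order. Entries are the parent network's edge
#' weights between the selected vertices; the diagonal is zero. This is
#' the topological half of the image-like representation: it preserves
#' the structure surrounding the centre vertex.
#'
#' @param network A [gene_network()].
#' @param field A [select_neighborhood()] result for this network.
#' @return Symmetric `m x m` matrix with gene names as dimnames.
#' @export
build_sub_adjacency <- function(network, field) {
  idx <- c(field$center, field$members)
  A <- network$weights[idx, idx, drop = FALSE]
  diag(A) <- 0
  A
}

#' Centroid-linkage distance between two disease classes
#'
#' Each class is located at the centroid (mean) of its member genes'
#' adjacency-row vectors in the given network; the distance between two
#' classes is the Euclidean distance between their centroids. This is the
#' linkage used to resolve multi-tag genes to a single class.
#'
#' @param t_a,t_b Class codes in `1..K`.
#' @param network A [gene_network()] providing the row vectors.
#' @param annotation A [disease_annotation()].
#' @return Non-negative distance; 0 when `t_a == t_b`.
#' @export
class_centroid_distance <- function(t_a, t_b, network, annotation) {
  D <- class_distance_matrix(network, annotation, classes = c(t_a, t_b))
  D[as.character(t_a), as.character(t_b)]
}

#' Pairwise centroid distances between disease classes
#'
#' @param network A [gene_network()].
#' @param annotation A [disease_annotation()].
#' @param classes Class codes to include (default all `1..K`).
#' @return `K x K` matrix of centroid distances; rows/columns of classes
#'   with no member gene in the network are `NA`.
#' @export
class_distance_matrix <- function(network, annotation,
                                  classes = seq_len(annotation$n_classes)) {
  classes <- unique(as.integer(classes))
  if (any(classes < 1 | classes > annotation$n_classes))
    stop("class codes must lie in 1..K")
  tagged <- names(annotation$tags)[lengths(annotation$tags) > 0]
  tagged <- intersect(tagged, network$genes)
  cent <- matrix(NA_real_, length(classes), ncol(network$weights))
  for (i in seq_along(classes)) {
    members <- tagged[vapply(tagged, function(g)
      classes[i] %in% annotation$tags[[g]], logical(1))]
    if (length(members) == 0) {
      if (length(classes) == 2 && classes[1] != classes[2])
        stop("class ", classes[i], " has no member gene in the network")
      next
    }
    cent[i, ] <- colMeans(network$weights[members, , drop = FALSE])
  }
  D <- as.matrix(stats::dist(cent))
  dimnames(D) <- list(classes, classes)
  D
}

# Resolve a tag set to the class closest to `ref` under distance matrix D;
# ties broken by the smallest class code. D rows/cols are named by code.
.closest_tag <- function(tag_set, ref, D) {
  d <- D[as.character(tag_set), as.character(ref)]
  if (anyNA(d))
    stop("centroid distance undefined for an empty class (codes ",
         paste(tag_set[is.na(d)], collapse = ","), ")")
  tag_set[which.min(d)]  # tag_set sorted ascending -> smallest-code ties
}

#' Resolve the centre vertex's tag
#'
#' The centre's tag `t_center` is: the target class itself if the centre
#' carries it; otherwise, for an annotated centre, the carried class whose
#' centroid is nearest the target class (smallest code on ties); 0 for an
#' unannotated centre.
#'
#' @param center Gene identifier.
#' @param annotation A [disease_annotation()].
#' @param dist_matrix Class-distance matrix from [class_distance_matrix()].
#' @return Integer tag (`0` = unannotated).
#' @export
assign_center_tag <- function(center, annotation, dist_matrix) {
  tags <- gene_tags(annotation, center)
  t_id <- annotation$target_class
  if (length(tags) == 0) return(0L)
  if (t_id %in% tags) return(t_id)
  .closest_tag(tags, t_id, dist_matrix)
}

#' Disease-class value of a neighbour
#'
#' The environmental value a neighbour contributes to the image diagonal:
#' 0 for an unannotated neighbour; `t_center / 4` if the neighbour carries
#' the centre's tag; otherwise `t_j / 4` for the neighbour's class nearest
#' the centre's tag (smallest code on ties). When the centre itself is
#' unannotated (`t_center == 0`) the target class serves as the reference
#' for the nearest-class rule.
#'
#' @param neighbor Gene identifier.
#' @param t_center Centre tag from [assign_center_tag()].
#' @param annotation A [disease_annotation()].
#' @param dist_matrix Class-distance matrix from [class_distance_matrix()].
#' @return Non-negative class value `c`.
#' @export
neighbor_class_value <- function(neighbor, t_center, annotation, dist_matrix) {
  tags <- gene_tags(annotation, neighbor)
  if (length(tags) == 0) return(0)
  ref <- if (t_center == 0) annotation$target_class else t_center
  if (ref %in% tags) return(ref / 4)
  .closest_tag(tags, ref, dist_matrix) / 4
}

#' Diagonal classification matrix of a neighbourhood
#'
#' Places the neighbours' class values on the diagonal: entry `(1,1)`
#' (the centre) is 0, entry `(p,p)` is the class value of the `(p-1)`-th
#' field member. All off-diagonal entries are zero.
#'
#' @param field A [select_neighborhood()] result.
#' @param c_values Numeric vector of length `m - 1`, aligned to
#'   `field$members`.
#' @return `m x m` diagonal matrix.
#' @export
build_classification_matrix <- function(field, c_values) {
  if (length(c_values) != field$m - 1)
    stop("c_values must have length m - 1")
  diag(c(0, c_values), nrow = field$m)
}

#' Image-like representation of one vertex
#'
#' Builds the `m x m` matrix `E = A + C` for a centre vertex: `A` is the
#' sub-adjacency of its node-induced sub-network, `C` the diagonal matrix
#' of its neighbours' disease-class values.
#'
#' @param network A [gene_network()].
#' @param annotation A [disease_annotation()].
#' @param order A [leaf_order()].
#' @param similarity A [compute_similarity()] result.
#' @param center Vertex index or gene name.
#' @param k Receptive-field radius.
#' @param m Image side length.
#' @param dist_matrix Optional precomputed [class_distance_matrix()].
#' @return An object of class `representation_image`: fields `E`, `A`,
#'   `C`, `center` (gene name), `t_center`, `members` (gene names).
#' @export
represent_vertex <- function(network, annotation, order, similarity,
                             center, k, m, dist_matrix = NULL) {
  if (is.character(center)) center <- match(center, network$genes)
  if (is.null(dist_matrix))
    dist_matrix <- class_distance_matrix(network, annotation)
  field <- select_neighborhood(center, order, similarity, k, m)
  A <- build_sub_adjacency(network, field)
  gene <- network$genes[center]
  members <- network$genes[field$members]
  t_center <- assign_center_tag(gene, annotation, dist_matrix)
  cv <- vapply(members, neighbor_class_value, numeric(1),
               t_center = t_center, annotation = annotation,
               dist_matrix = dist_matrix)
  C <- build_classification_matrix(field, unname(cv))
  dimnames(C) <- dimnames(A)
  structure(
    list(E = A + C, A = A, C = C, center = gene, t_center = t_center,
         members = members),
    class = "representation_image"
  )
}

#' Baseline representation without environmental characteristics
#'
#' The no-environment baseline: neighbours are simply the `m - 1`
#' consecutive successors of the centre in the leaf order (wrapping at the
#' end of the sequence), and the image is the bare sub-adjacency `E = A`
#' with no classification matrix.
#'
#' @param network A [gene_network()].
#' @param order A [leaf_order()].
#' @param center Vertex index or gene name.
#' @param m Image side length.
#' @return A `representation_image` with `C = 0` and `t_center = NA`.
#' @export
represent_baseline <- function(network, order, center, m) {
  if (is.character(center)) center <- match(center, network$genes)
  n <- length(order$order)
  if (m > n) stop("m exceeds the number of vertices")
  p <- order$position[center]
  succ <- ((p + seq_len(m - 1) - 1) %% n) + 1
  field <- structure(
    list(center = center, radius = NA_integer_,
         members = order$order[succ], m = m),
    class = "neighborhood_field"
  )
  A <- build_sub_adjacency(network, field)
  C <- matrix(0, m, m, dimnames = dimnames(A))
  structure(
    list(E = A, A = A, C = C, center = network$genes[center],
         t_center = NA_integer_, members = network$genes[field$members]),
    class = "representation_image"
  )
}

#' Represent a set of vertices as an image stack
#'
#' Runs the full representation pipeline — similarity, leaf order,
#' receptive-field neighbour selection, sub-adjacency and classification
#' matrix — once per requested gene and stacks the resulting `m x m`
#' images. With `style = "baseline"` the no-environment variant
#' ([represent_baseline()]) is used instead.
#'
#' @param network A [gene_network()].
#' @param annotation A [disease_annotation()] (ignored for the baseline).
#' @param k Receptive-field radius; default `min(n - 1, 3 * m)`.
#' @param m Image side length (default 21, one less than a 22-class
#'   disease catalogue with one "unclassified" class).
#' @param genes Genes to represent (default: all).
#' @param cap Similarity cap for identical rows.
#' @param use_sqrt Passed to [compute_similarity()].
#' @param style `"environment"` (default) or `"baseline"`.
#' @return An object of class `representation_dataset`: `images` (array
#'   `N x m x m`), `genes`, `t_center`, and `params` (m, k, cap, style,
#'   target class, network name).
#' @export
represent_all <- function(network, annotation, k = NULL, m = 21,
                          genes = NULL, cap = 1e12, use_sqrt = FALSE,
                          style = c("environment", "baseline")) {
  style <- match.arg(style)
  n <- length(network$genes)
  if (is.null(k)) k <- min(n - 1, 3 * m)
  if (!(n > k && k > m)) stop("need n > k > m")
  if (is.null(genes)) genes <- network$genes
  sim <- compute_similarity(network, cap = cap, use_sqrt = use_sqrt)
  ord <- leaf_order(sim)
  D <- if (style == "environment") class_distance_matrix(network, annotation)
  images <- array(0, dim = c(length(genes), m, m),
                  dimnames = list(genes, NULL, NULL))
  t_center <- rep(NA_integer_, length(genes))
  for (i in seq_along(genes)) {
    img <- if (style == "environment") {
      represent_vertex(network, annotation, ord, sim, genes[i], k, m,
                       dist_matrix = D)
    } else {
      represent_baseline(network, ord, genes[i], m)
    }
    images[i, , ] <- img$E
    t_center[i] <- img$t_center
  }
  structure(
    list(images = images, genes = genes, t_center = t_center,
         params = list(m = m, k = k, cap = cap, use_sqrt = use_sqrt,
                       style = style,
                       target_class = annotation$target_class,
                       network = network$name)),
    class = "representation_dataset"
  )
}

#' @export
print.representation_dataset <- function(x, ...) {
  cat(sprintf(
    "representation_dataset: %d images of %dx%d (style '%s', network '%s')\n",
    dim(x$images)[1], x$params$m, x$params$m, x$params$style,
    x$params$network
  ))
  invisible(x)
}

#' Fuse several network views into one image stack
#'
#' Multi-network fusion "adds the image-like matrices evenly": the
#' neighbourhood field of each centre is fixed on the reference view, each
#' view's sub-adjacency is read off at that fixed field, and the fused
#' image is the elementwise mean across views of `A_view + C`, with the
#' classification matrix `C` computed once from the reference view. Binary
#' views enter as 0/1; weighted views are min-max scaled to `[0, 1]`
#' beforehand so no single view dominates the average.
#'
#' @param views List of [gene_network()]s sharing one gene ordering
#'   (see [harmonize()]).
#' @param reference Index (or name) of the reference view in `views`.
#' @param annotation A [disease_annotation()].
#' @param k,m,cap,use_sqrt As in [represent_all()].
#' @param genes Genes to represent (default: all).
#' @return A `representation_dataset` of fused images.
#' @export
fuse_networks <- function(views, reference, annotation, k = NULL, m = 21,
                          genes = NULL, cap = 1e12, use_sqrt = FALSE) {
  if (is.character(reference))
    reference <- match(reference, vapply(views, `[[`, character(1), "name"))
  if (is.na(reference) || reference < 1 || reference > length(views))
    stop("reference must identify one of the views")
  g0 <- views[[1]]$genes
  same <- vapply(views, function(v) identical(v$genes, g0), logical(1))
  if (!all(same)) stop("views must share one gene ordering; run harmonize() first")
  scaled <- lapply(views, function(v) {
    if (v$is_binary || max(v$weights) == 0) return(v)
    gene_network(v$genes, v$weights / max(v$weights), name = v$name,
                 is_binary = FALSE)
  })
  ref <- scaled[[reference]]
  n <- length(ref$genes)
  if (is.null(k)) k <- min(n - 1, 3 * m)
  if (!(n > k && k > m)) stop("need n > k > m")
  if (is.null(genes)) genes <- ref$genes
  sim <- compute_similarity(ref, cap = cap, use_sqrt = use_sqrt)
  ord <- leaf_order(sim)
  D <- class_distance_matrix(ref, annotation)
  images <- array(0, dim = c(length(genes), m, m),
                  dimnames = list(genes, NULL, NULL))
  t_center <- rep(NA_integer_, length(genes))
  for (i in seq_along(genes)) {
    img <- represent_vertex(ref, annotation, ord, sim, genes[i], k, m,
                            dist_matrix = D)
    idx <- match(c(img$center, img$members), g0)
    A_mean <- Reduce(`+`, lapply(scaled, function(v) {
      A <- v$weights[idx, idx, drop = FALSE]; diag(A) <- 0; A
    })) / length(scaled)
    images[i, , ] <- A_mean + img$C
    t_center[i] <- img$t_center
  }
  structure(
    list(images = images, genes = genes, t_center = t_center,
         params = list(m = m, k = k, cap = cap, use_sqrt = use_sqrt,
                       style = "fused", target_class = annotation$target_class,
                       network = ref$name, n_views = length(views))),
    class = "representation_dataset"
  )
}
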