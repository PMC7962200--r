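as_weight_matrix <- function(graph) {
  if (inherits(graph, "weighted_visibility_graph")) return(graph$weights)
  if (is.matrix(graph) && nrow(graph) == ncol(graph)) return(graph)
  stop("expected a weighted_visibility_graph or a square weight matrix")
}

#' Node strengths (weighted degrees)
#'
#' The strength of node i is the sum of its incident edge weights,
#' \eqn{d_i = \sum_{j \ne i} w_{ij}}. The diagonal is excluded: a node's
#' self-weight never contributes.
#'
#' @param graph a `weighted_visibility_graph` or square weight matrix.
#' @return numeric vector of per-node strengths.
#' @export
weighted_degrees <- function(graph) {
  w <- as_weight_matrix(graph)
  rowSums(w) - diag(w)
}

#' Average weighted degree
#'
#' Mean node strength over all N nodes of the graph.
#'
#' @inheritParams weighted_degrees
#' @return a single number.
#' @export
average_weighted_degree <- function(graph) {
  mean(weighted_degrees(graph))
}

#' Deviation of the weighted degree
#'
#' Sample standard deviation (divisor N - 1) of the node strengths.
#'
#' @inheritParams weighted_degrees
#' @return a single nonnegative number.
#' @export
degree_deviation <- function(graph) {
  stats::sd(weighted_degrees(graph))
}

#' Weighted clustering coefficient
#'
#' Per node,
#' \deqn{C_i = \frac{\sum_{\{j,k\}} w_{ij} w_{ik} w_{jk}}
#'                  {\sum_{\{j,k\}} w_{ij} w_{ik}}}
#' where both sums run over unordered pairs of distinct neighbours of i
#' (counting ordered pairs twice leaves the ratio unchanged); a node with
#' fewer than two weighted neighbours has a zero denominator and is assigned
#' C_i = 0. The network coefficient is the mean of C_i over all N nodes.
#' Raw weights enter as stored — no normalization by the maximum weight.
#'
#' Computed through sparse matrix products: the triangle sum per node is the
#' diagonal of W^3 and the denominator is \eqn{d_i^2 - \sum_j w_{ij}^2}, so
#' the cost scales with the number of edges, not N^3.
#'
#' @inheritParams weighted_degrees
#' @return list with `per_node` (numeric vector C_i) and `network` (mean).
#' @export
weighted_clustering <- function(graph) {
  w <- as_weight_matrix(graph)
  diag(w) <- 0
  idx <- which(w != 0, arr.ind = TRUE)
  ws <- Matrix::sparseMatrix(i = idx[, 1], j = idx[, 2], x = w[idx],
                             dims = dim(w))
  clustering_from_sparse(ws)
}

clustering_from_sparse <- function(ws) {
  w2 <- ws %*% ws
  num <- Matrix::rowSums(w2 * ws)          # diag(W^3): ordered neighbour pairs
  d <- Matrix::rowSums(ws)
  den <- d^2 - Matrix::rowSums(ws^2)       # sum_{j != k} w_ij w_ik
  ci <- ifelse(den > 0, num / pmax(den, .Machine$double.xmin), 0)
  list(per_node = as.numeric(ci), network = mean(ci))
}

#' Entropy of the node clustering coefficients
#'
#' Normalizes the per-node weighted clustering coefficients to a probability
#' distribution \eqn{P_i = C_i / \sum_j C_j} and returns its Shannon entropy
#' \eqn{-\sum_i P_i \log P_i} (natural log by default; zero coefficients
#' contribute nothing). A triangle-free graph has no distribution to measure:
#' the entropy is reported as 0 with a warning.
#'
#' @inheritParams weighted_degrees
#' @param log_base base of the logarithm; `exp(1)` (nats, default) or `2`.
#' @return a single nonnegative number.
#' @export
clustering_entropy <- function(graph, log_base = exp(1)) {
  ci <- weighted_clustering(graph)$per_node
  total <- sum(ci)
  if (total <= 0) {
    warning("graph has no triangles; clustering entropy reported as 0")
    return(0)
  }
  p <- ci[ci > 0] / total
  -sum(p * log(p, base = log_base))
}

network_feature_names <- c("avg_weighted_degree", "degree_deviation",
                           "weighted_clustering", "clustering_entropy")

# Fast path shared by the matrix-facing API and the pipeline: statistics
# straight from a 1-based edge list, never materializing a dense matrix.
wnet_stats_from_edges <- function(edges, w, n, log_base = exp(1)) {
  ws <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                             j = c(edges[, 2], edges[, 1]),
                             x = c(w, w), dims = c(n, n))
  d <- Matrix::rowSums(ws)
  cl <- clustering_from_sparse(ws)
  ent <- if (sum(cl$per_node) <= 0) {
    warning("graph has no triangles; clustering entropy reported as 0")
    0
  } else {
    p <- cl$per_node[cl$per_node > 0] / sum(cl$per_node)
    -sum(p * log(p, base = log_base))
  }
  c(avg_weighted_degree = mean(d),
    degree_deviation = stats::sd(d),
    weighted_clustering = cl$network,
    clustering_entropy = ent)
}

wnet_feature_vector <- function(graph, log_base = exp(1)) {
  el <- graph_edgelist(graph)
  wnet_stats_from_edges(cbind(el$i, el$j), el$weight,
                        nrow(graph$weights), log_base)
}

#' Weighted-network feature vector of a segment
#'
#' Maps the segment to its forward and backward weighted visibility graphs,
#' computes the four network statistics (average weighted degree, degree
#' deviation, weighted clustering coefficient, clustering entropy) on each,
#' and optionally fuses the two directions by elementwise sum.
#'
#' Band-passed EEG is zero-mean while the angle weights presume nonnegative
#' bar heights, so by default each segment is shifted so its minimum is 0
#' before graph construction. The shift leaves the visibility pattern
#' untouched (visibility is invariant to adding a constant) and guarantees
#' nonnegative weights; set `shift_min = FALSE` to use raw amplitudes, as the
#' worked example in the vignette does.
#'
#' @param segment a [ts_segment] or numeric vector.
#' @param fuse if `TRUE` (default) return the forward + backward sum; else a
#'   list with `forward` and `backward` vectors.
#' @param base_kind `"hvg"` (default) or `"vg"` edge pattern.
#' @param shift_min shift the segment minimum to zero first (default `TRUE`).
#' @param log_base entropy logarithm base, see [clustering_entropy()].
#' @return named numeric vector of 4 features, or a list of two such vectors.
#' @examples
#' extract_network_features(toy_series(), shift_min = FALSE)
#' @export
extract_network_features <- function(segment, fuse = TRUE,
                                     base_kind = c("hvg", "vg"),
                                     shift_min = TRUE, log_base = exp(1)) {
  base_kind <- match.arg(base_kind)
  seg <- as_segment(segment)
  x <- seg$values
  if (shift_min) x <- x - min(x)
  n <- length(x)
  # the visibility pattern is direction-independent; compute it once
  edges <- if (base_kind == "hvg") hvg_edges_cpp(x)
           else vg_edges_cpp(x, 1e-12)
  i <- edges[, 1]; j <- edges[, 2]
  fv <- wnet_stats_from_edges(edges, forward_weight(x[i], x[j], j - i),
                              n, log_base)
  bv <- wnet_stats_from_edges(edges, backward_weight(x[i], x[j], j - i),
                              n, log_base)
  if (fuse) fv + bv else list(forward = fv, backward = bv)
}
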