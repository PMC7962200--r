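#' @useDynLib hvgnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_visibility_graph <- function(adjacency, kind) {
  structure(list(adjacency = adjacency, kind = kind),
            class = "visibility_graph")
}

edges_to_adjacency <- function(edges, n) {
  a <- matrix(0L, n, n)
  a[edges] <- 1L
  a[edges[, 2:1, drop = FALSE]] <- 1L
  a
}

#' Natural visibility graph of a time series
#'
#' Connects samples i < j whenever every intermediate sample lies strictly
#' below the straight line joining the two bar tops. An intermediate exactly
#' on the chord blocks visibility (the comparison uses an absolute slope
#' tolerance of `tol`, so exactly collinear runs, e.g. a linear ramp, reduce
#' to a path). Adjacent samples are always connected.
#'
#' @param segment a [ts_segment] or numeric vector.
#' @param tol absolute tolerance on the slope comparison; an intermediate
#'   within `tol` of the chord slope blocks.
#' @return a `visibility_graph`: list with the N x N binary `adjacency`
#'   matrix and `kind = "vg"`.
#' @seealso [build_hvg()] for the horizontal variant.
#' @examples
#' g <- build_vg(toy_series())
#' sum(g$adjacency) / 2  # number of edges
#' @export
build_vg <- function(segment, tol = 1e-12) {
  seg <- as_segment(segment)
  edges <- vg_edges_cpp(seg$values, tol)
  new_visibility_graph(edges_to_adjacency(edges, length(seg$values)), "vg")
}

#' Horizontal visibility graph of a time series
#'
#' Connects samples i < j whenever every intermediate sample is strictly
#' lower than both endpoints; an intermediate equal to either endpoint
#' blocks. Adjacent samples are always connected, and the edge set is always
#' a subset of the natural visibility graph's. Uses a linear-time monotone
#' stack sweep.
#'
#' @inheritParams build_vg
#' @return a `visibility_graph` with `kind = "hvg"`.
#' @examples
#' g <- build_hvg(toy_series())
#' which(g$adjacency[1, ] == 1)  # nodes visible from the first sample
#' @export
build_hvg <- function(segment) {
  seg <- as_segment(segment)
  edges <- hvg_edges_cpp(seg$values)
  new_visibility_graph(edges_to_adjacency(edges, length(seg$values)), "hvg")
}

#' @export
print.visibility_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("<visibility_graph> kind=%s, %d nodes, %d edges\n",
              x$kind, n, sum(x$adjacency) / 2L))
  invisible(x)
}

#' Forward and backward visibility-angle edge weights
#'
#' The weight of a visible pair (i, j), i before j, is the angle (radians)
#' between the chord joining the two bar tops and the line from one bar top
#' to the foot of the other bar. Reading the series forward the anchor is
#' the earlier bar:
#' \deqn{w^f_{ij} = \arctan\frac{x_j - x_i}{t_j - t_i} + \arctan\frac{x_i}{t_j - t_i}}
#' and reading it backward the anchor is the later bar:
#' \deqn{w^b_{ij} = \arctan\frac{x_i - x_j}{t_j - t_i} + \arctan\frac{x_j}{t_j - t_i}.}
#' For any pair the two directions sum to
#' \eqn{\arctan(x_i/\Delta t) + \arctan(x_j/\Delta t)}. Nonnegative
#' amplitudes give weights in (-pi/2, pi); strictly positive endpoints give
#' weights in (0, pi).
#'
#' @param x_i,x_j amplitudes at the earlier and later node.
#' @param dt positive integer time gap t_j - t_i.
#' @return angle in radians (vectorized over its arguments).
#' @examples
#' forward_weight(7, 8, 2)   # 1.756 to three decimals
#' backward_weight(7, 8, 2)  # 0.862 to three decimals
#' @export
forward_weight <- function(x_i, x_j, dt) {
  if (any(dt <= 0)) stop("time gap dt must be positive")
  atan((x_j - x_i) / dt) + atan(x_i / dt)
}

#' @rdname forward_weight
#' @export
backward_weight <- function(x_i, x_j, dt) {
  if (any(dt <= 0)) stop("time gap dt must be positive")
  atan((x_i - x_j) / dt) + atan(x_j / dt)
}

new_weighted_graph <- function(weights, direction, base_kind) {
  structure(list(weights = weights, direction = direction,
                 base_kind = base_kind),
            class = "weighted_visibility_graph")
}

build_weighted <- function(seg, direction, base_kind, tol) {
  x <- seg$values
  n <- length(x)
  edges <- if (base_kind == "hvg") hvg_edges_cpp(x) else vg_edges_cpp(x, tol)
  i <- edges[, 1]; j <- edges[, 2]
  w <- if (direction == "forward")
    forward_weight(x[i], x[j], j - i)
  else
    backward_weight(x[i], x[j], j - i)
  wm <- matrix(0, n, n)
  wm[edges] <- w
  wm[edges[, 2:1, drop = FALSE]] <- w
  new_weighted_graph(wm, direction, base_kind)
}

#' Weighted horizontal visibility graph (FWHVG / BWHVG)
#'
#' Builds the horizontal visibility graph of the segment and attaches the
#' direction-dependent angle weight of [forward_weight()] /
#' [backward_weight()] to every visible pair. The nonzero off-diagonal
#' pattern of the weight matrix equals the HVG adjacency; weights are stored
#' symmetrically (each weight is computed once with the earlier node as i)
#' and the diagonal is zero — no self-edges, and all network statistics run
#' over neighbours j != i.
#'
#' @inheritParams build_vg
#' @param direction `"forward"` or `"backward"`.
#' @return a `weighted_visibility_graph`: list with the N x N `weights`
#'   matrix, `direction`, and `base_kind`.
#' @examples
#' wf <- build_weighted_hvg(toy_series(), "forward")
#' round(wf$weights[1, 3], 3)  # 1.756
#' @export
build_weighted_hvg <- function(segment, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  build_weighted(as_segment(segment), direction, "hvg", 0)
}

#' Weighted natural visibility graph (FWVG / BWVG)
#'
#' Same angle weights as [build_weighted_hvg()], attached to the natural
#' visibility pattern of [build_vg()] instead of the horizontal one.
#'
#' @inheritParams build_vg
#' @inheritParams build_weighted_hvg
#' @return a `weighted_visibility_graph` with `base_kind = "vg"`.
#' @export
build_weighted_vg <- function(segment, direction = c("forward", "backward"),
                              tol = 1e-12) {
  direction <- match.arg(direction)
  build_weighted(as_segment(segment), direction, "vg", tol)
}

#' @export
print.weighted_visibility_graph <- function(x, ...) {
  n <- nrow(x$weights)
  cat(sprintf("<weighted_visibility_graph> %s %s, %d nodes, %d weighted pairs\n",
              x$direction, toupper(x$base_kind), n,
              sum(x$weights != 0) / 2L))
  invisible(x)
}

#' Edge list of a (weighted) visibility graph
#'
#' @param graph a `visibility_graph` or `weighted_visibility_graph`.
#' @return a data frame with 1-based columns `i`, `j` (i < j) and, for
#'   weighted graphs, `weight`.
#' @export
graph_edgelist <- function(graph) {
  m <- if (inherits(graph, "weighted_visibility_graph")) graph$weights
       else graph$adjacency
  idx <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(i = idx[, 1], j = idx[, 2])
  if (inherits(graph, "weighted_visibility_graph"))
    out$weight <- m[idx]
  out
}

#' Write / read a graph matrix as delimited text
#'
#' Plain tab-separated export of the adjacency or weight matrix; 1-based
#' edge lists are available through [graph_edgelist()].
#'
#' @param graph a graph object.
#' @param path file path.
#' @export
write_graph_matrix <- function(graph, path) {
  m <- if (inherits(graph, "weighted_visibility_graph")) graph$weights
       else graph$adjacency
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_matrix
#' @export
read_graph_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}
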