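#' Symmetric normalization of a skeleton adjacency matrix
#'
#' Computes the self-looped, degree-symmetrized adjacency
#' \deqn{G_t = \Lambda^{-1/2} (\bar G + I) \Lambda^{-1/2},}
#' where \eqn{\bar G} is the binary bone adjacency and
#' \eqn{\Lambda_{xx} = \sum_y \bar G_{xy} + 1} (the degree including the
#' self-loop). This is the operator every spatial graph-convolution layer
#' aggregates with; its eigenvalues lie in \eqn{[-1, 1]}.
#'
#' @param adjacency V x V symmetric 0/1 matrix with zero diagonal.
#' @return list with `normalized` (V x V symmetric matrix) and `degree`
#'   (length-V vector, diagonal of \eqn{\Lambda}).
#' @examples
#' normalize_adjacency(matrix(c(0, 1, 1, 0), 2))$normalized  # all 0.5
#' @export
normalize_adjacency <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (!isTRUE(all.equal(a, t(a), tolerance = 0, check.attributes = FALSE))) {
    stop("adjacency must be symmetric")
  }
  if (!all(a %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (any(diag(a) != 0)) stop("adjacency must have a zero diagonal")
  degree <- rowSums(a) + 1
  dinv <- 1 / sqrt(degree)
  normalized <- (a + diag(nrow(a))) * tcrossprod(dinv)
  list(normalized = normalized, degree = degree)
}

#' Centroid-distance partition of the joint neighborhoods
#'
#' Splits the normalized adjacency into three subset matrices by comparing,
#' for every root joint x and every neighbor y (including x itself via the
#' self-loop), the template-pose distances to the skeleton's center of
#' gravity (the mean coordinate of all joints):
#' label 0 (*stationary*) when \eqn{r_y = r_x} within `tol`,
#' label 1 (*centripetal*) when \eqn{r_y < r_x},
#' label 2 (*centrifugal*) when \eqn{r_y > r_x}.
#' Each subset keeps the corresponding entries of `normalized` and zeros the
#' rest, so the three subsets have disjoint support and sum back to the full
#' normalized adjacency. Rows index the root joint x, columns the neighbor y.
#'
#' The partition is computed once per layout from the static template pose,
#' so the per-subset learnable parameters of the network have a fixed
#' support.
#'
#' @param layout the `skeleton_layout` whose template pose defines the
#'   center of gravity.
#' @param normalized the matrix returned by [normalize_adjacency()] on
#'   `adjacency_from_layout(layout)`.
#' @param tol tolerance for distance equality (default `1e-6`).
#' @return list with `subsets` (list of three V x V matrices, in order
#'   stationary / centripetal / centrifugal) and `subset_labels` (V x V
#'   integer matrix with entries in \{-1, 0, 1, 2\}; -1 marks non-neighbors).
#' @export
partition_spatial <- function(layout, normalized, tol = 1e-6) {
  stopifnot(inherits(layout, "skeleton_layout"))
  v <- layout$num_joints
  normalized <- as.matrix(normalized)
  if (nrow(normalized) != v || ncol(normalized) != v) {
    stop("normalized matrix is ", nrow(normalized), "x", ncol(normalized),
         " but layout '", layout$name, "' has ", v, " joints")
  }
  centroid <- colMeans(layout$template_pose)
  radius <- sqrt(rowSums(sweep(layout$template_pose, 2L, centroid)^2))
  labels <- matrix(-1L, v, v)
  support <- normalized != 0
  for (x in seq_len(v)) {
    for (y in which(support[x, ])) {
      d <- radius[y] - radius[x]
      labels[x, y] <- if (abs(d) <= tol) 0L else if (d < 0) 1L else 2L
    }
  }
  subsets <- lapply(0:2, function(z) {
    s <- matrix(0, v, v)
    s[labels == z] <- normalized[labels == z]
    s
  })
  list(subsets = subsets, subset_labels = labels)
}

#' All graph tensors of a skeleton layout
#'
#' Convenience wrapper bundling [adjacency_from_layout()],
#' [normalize_adjacency()] and [partition_spatial()].
#'
#' @param layout a `skeleton_layout`.
#' @inheritParams partition_spatial
#' @return A `graph_tensors` object: list with `adjacency`, `degree`,
#'   `normalized`, `subsets` (list of 3 matrices) and `subset_labels`.
#' @examples
#' g <- graph_tensors(build_layout("synthetic20"))
#' max(abs(Reduce(`+`, g$subsets) - g$normalized))  # 0: partition completeness
#' @export
graph_tensors <- function(layout, tol = 1e-6) {
  adjacency <- adjacency_from_layout(layout)
  norm <- normalize_adjacency(adjacency)
  part <- partition_spatial(layout, norm$normalized, tol = tol)
  structure(
    list(adjacency = adjacency, degree = norm$degree,
         normalized = norm$normalized, subsets = part$subsets,
         subset_labels = part$subset_labels, layout_name = layout$name),
    class = "graph_tensors"
  )
}

#' @export
print.graph_tensors <- function(x, ...) {
  cat("<graph_tensors> layout ", x$layout_name, ": V = ", nrow(x$normalized),
      ", subset support sizes ",
      paste(vapply(x$subsets, function(s) sum(s != 0), 0L), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}
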