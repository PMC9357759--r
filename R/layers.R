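#' Layer parameters for one ST-GCN block
#'
#' Creates the learnable state of a single block: three per-subset 1x1
#' channel transforms (one `C_out x C_in` matrix per partition subset),
#' three per-subset `V x V` edge-importance masks initialized to all ones
#' (identity attention; they are multiplied elementwise with the adjacency
#' subsets and learned during training, acting as spatial attention over
#' bone connections), two temporal filter banks of kernel extent `gamma` and
#' `2 * gamma` each holding half the output channels, batch-normalization
#' parameters, and an optional 1x1 residual projection when `c_in != c_out`.
#'
#' @param c_in,c_out input/output channel counts (`c_out` must be even).
#' @param v joint count of the graph the block operates on.
#' @param gamma base temporal kernel extent (default 9; the long branch
#'   uses `2 * gamma`).
#' @param stride temporal stride (default 1).
#' @param mode `"multiscale"` (two kernel extents, the default) or
#'   `"single"` (all filters at extent `gamma` — the single-scale ablation
#'   arm).
#' @param seed optional seed for reproducible initialization.
#' @return A list of block parameters, suitable for [spatial_graph_conv()],
#'   [ms_tcn()] and [stgcn_block()].
#' @export
layer_parameters <- function(c_in, c_out, v, gamma = 9L, stride = 1L,
                             mode = c("multiscale", "single"), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) {
    restore <- .local_seed(seed)
    on.exit(restore(), add = TRUE)
  }
  .block_init(c_in, c_out, v, gamma, stride, mode)
}

#' Subset-wise spatial graph convolution
#'
#' Aggregates joint neighborhoods with the three partition subsets of the
#' normalized adjacency:
#' \deqn{f_{out} = \sum_z \Theta_z \, f_{in} \, (G_z \odot W_z),}
#' where \eqn{\Theta_z} is the subset's 1x1 channel transform, \eqn{G_z} the
#' subset matrix and \eqn{W_z} its learnable edge-importance mask
#' (elementwise product). The frame count is unchanged.
#'
#' @param features numeric array (C_in, T, V) — one sample's features.
#' @param graph a [graph_tensors()] object (3 subsets).
#' @param params block parameters from [layer_parameters()] (uses the
#'   `$sgc` component).
#' @return numeric array (C_out, T, V).
#' @export
spatial_graph_conv <- function(features, graph, params) {
  stopifnot(length(dim(features)) == 3L)
  if (length(graph$subsets) != 3L) stop("graph must carry 3 subsets")
  v <- dim(features)[3L]
  if (v != nrow(graph$normalized)) {
    stop("features have ", v, " joints but graph has ",
         nrow(graph$normalized))
  }
  x <- .ctv_to_engine(features)
  out <- .sgc_fwd(x, graph$subsets, params$sgc$theta, params$sgc$masks,
                  params$sgc$bias)$y
  .engine_to_ctv(out)
}

# (C, T, V) single-sample view <-> (C, V, 1, T) engine layout
.ctv_to_engine <- function(features) {
  x <- aperm(features, c(1L, 3L, 2L))
  dim(x) <- c(dim(features)[1L], dim(features)[3L], 1L, dim(features)[2L])
  x
}

.engine_to_ctv <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L], d[2L], d[4L])
  aperm(x, c(1L, 3L, 2L))
}

#' Multiscale temporal convolution block
#'
#' Convolves along the frame axis with two parallel filter banks — half the
#' channels at kernel extent `gamma`, half at `2 * gamma` — concatenates the
#' branch outputs on the channel axis, batch-normalizes, adds the block
#' input as a residual, and applies ReLU. At stride 1 the frame count is
#' conserved by same-padding (left `ceil((k-1)/2)`, right `floor((k-1)/2)`).
#' With all filters and biases zero the block is the identity on
#' non-negative input.
#'
#' In `"single"` mode the block holds one bank of all `C` filters at extent
#' `gamma`, reproducing a plain temporal convolution (the single-scale
#' ablation arm).
#'
#' @param features numeric array (C, T, V), C even.
#' @param params block parameters from [layer_parameters()] (uses `$tcn`
#'   and `$bn2`).
#' @param stride temporal stride (default the block's configured stride).
#' @return numeric array (C, ceil(T / stride), V).
#' @export
ms_tcn <- function(features, params, stride = params$stride) {
  stopifnot(length(dim(features)) == 3L)
  c_n <- dim(features)[1L]
  if (c_n %% 2L != 0L && length(params$tcn) > 1L) {
    stop("multiscale temporal convolution needs an even channel count")
  }
  x <- .ctv_to_engine(features)
  tc <- lapply(params$tcn, function(br) .tconv_fwd(x, br$w, br$b, stride))
  tcat <- if (length(tc) == 1L) tc[[1L]]$y else {
    yd <- dim(tc[[1L]]$y)
    out <- array(0, c(c_n, yd[2L], yd[3L], yd[4L]))
    out[seq_len(yd[1L]), , , ] <- tc[[1L]]$y
    out[yd[1L] + seq_len(dim(tc[[2L]]$y)[1L]), , , ] <- tc[[2L]]$y
    out
  }
  t_dims <- dim(tcat)
  bn <- .bn_fwd(matrix(tcat, t_dims[1L]), params$bn2, training = TRUE)
  t_keep <- seq(1L, dim(x)[4L], by = stride)
  pre <- array(bn$y, t_dims) + x[, , , t_keep, drop = FALSE]
  .engine_to_ctv(.relu_fwd(pre)$y)
}

#' One full spatio-temporal graph-convolution block
#'
#' Composition used by the classifier: spatial graph convolution, batch
#' normalization, ReLU, then the multiscale temporal convolution with its
#' residual, plus a block-level residual path (identity, or a strided 1x1
#' projection when the channel widths differ).
#'
#' @param features numeric array (C_in, T, V).
#' @param graph a [graph_tensors()] object.
#' @param params block parameters from [layer_parameters()].
#' @return numeric array (C_out, ceil(T / stride), V).
#' @export
stgcn_block <- function(features, graph, params) {
  stopifnot(length(dim(features)) == 3L)
  x <- .ctv_to_engine(features)
  out <- .block_fwd(x, params, graph$subsets, training = TRUE)$y
  .engine_to_ctv(out)
}
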