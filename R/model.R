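#' Model configuration
#'
#' Architecture settings of the MS-ST-GCN classifier. The defaults are a
#' 10-block stack with temporal stride 1 throughout — the standard ST-GCN
#' depth — with a lightweight channel plan (four blocks at 16, three at
#' 32, three at 64 channels) chosen so the default model stays well under
#' one million trainable parameters; see the methods vignette for the audit.
#'
#' @param num_classes number of action classes.
#' @param num_layers number of stacked blocks (default 10).
#' @param channel_plan integer vector of per-block output channels (all
#'   even; length `num_layers`).
#' @param gamma base temporal kernel extent (default 9; the multiscale
#'   branch pairs it with `2 * gamma = 18`).
#' @param strides per-block temporal strides (default all 1).
#' @param dropout dropout probability applied to the pooled features during
#'   training (default 0.25).
#' @param layout_name skeleton layout identifier (default `"synthetic20"`).
#' @param temporal_mode `"multiscale"` (default) or `"single"` (single-scale
#'   temporal convolution, the ablation arm).
#' @return A `model_config` list.
#' @export
model_config <- function(num_classes,
                         num_layers = 10L,
                         channel_plan = c(16L, 16L, 16L, 16L, 32L, 32L, 32L,
                                          64L, 64L, 64L)[seq_len(num_layers)],
                         gamma = 9L,
                         strides = rep(1L, num_layers),
                         dropout = 0.25,
                         layout_name = "synthetic20",
                         temporal_mode = c("multiscale", "single")) {
  temporal_mode <- match.arg(temporal_mode)
  num_layers <- as.integer(num_layers)
  channel_plan <- as.integer(channel_plan)
  strides <- as.integer(strides)
  if (length(channel_plan) != num_layers) {
    stop("channel_plan must have one entry per layer (", num_layers, ")")
  }
  if (length(strides) != num_layers) {
    stop("strides must have one entry per layer (", num_layers, ")")
  }
  if (any(channel_plan %% 2L != 0L)) {
    stop("all channel counts must be even (the multiscale filter split ",
         "halves them)")
  }
  if (gamma < 1L) stop("gamma must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(
    list(num_classes = as.integer(num_classes), num_layers = num_layers,
         channel_plan = channel_plan, gamma = as.integer(gamma),
         strides = strides, dropout = dropout, layout_name = layout_name,
         temporal_mode = temporal_mode),
    class = "model_config"
  )
}

#' Build an untrained MS-ST-GCN classifier
#'
#' Assembles the full network: an input batch-normalization layer over the
#' flattened (channel, joint, person) axis, `num_layers` stacked
#' [stgcn_block()]s sharing the layout's partitioned graph, global average
#' pooling over frames and joints, a mean over persons, dropout, a linear
#' classification layer and softmax.
#'
#' @param config a [model_config()].
#' @param in_channels input channel count C (3 for (x, y, conf) pose data,
#'   4 for the synthetic generator's (x, y, z, conf)).
#' @param persons person slots M the model is built for (default 2).
#' @param seed optional seed for reproducible weight initialization.
#' @return An `msstgcn_model` object.
#' @export
build_model <- function(config, in_channels = 4L, persons = 2L,
                        seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  if (!is.null(seed)) {
    restore <- .local_seed(seed)
    on.exit(restore(), add = TRUE)
  }
  layout <- build_layout(config$layout_name)
  graph <- graph_tensors(layout)
  v <- layout$num_joints
  blocks <- vector("list", config$num_layers)
  c_prev <- as.integer(in_channels)
  for (i in seq_len(config$num_layers)) {
    blocks[[i]] <- .block_init(c_prev, config$channel_plan[i], v,
                               config$gamma, config$strides[i],
                               config$temporal_mode)
    c_prev <- config$channel_plan[i]
  }
  k <- config$num_classes
  fc <- list(w = .he_init(c_prev, c(k, c_prev)), b = rep(0, k))
  structure(
    list(config = config, layout = layout, graph = graph,
         in_channels = as.integer(in_channels), persons = as.integer(persons),
         data_bn = .bn_init(in_channels * v * persons),
         blocks = blocks, fc = fc),
    class = "msstgcn_model"
  )
}

#' @export
print.msstgcn_model <- function(x, ...) {
  cat("<msstgcn_model> ", x$config$num_layers, " blocks (",
      paste(x$config$channel_plan, collapse = "-"), "), gamma=",
      x$config$gamma, "/", 2L * x$config$gamma, " (", x$config$temporal_mode,
      "), layout ", x$layout$name, ", ", x$config$num_classes, " classes, ",
      format(count_parameters(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

#' Class probabilities for a batch
#'
#' Runs the full network forward in inference mode (batch-normalization uses
#' running statistics, dropout off). Softmax guarantees each output row is a
#' probability vector.
#'
#' @param model an `msstgcn_model` (trained or untrained).
#' @param batch either a `skeleton_dataset` or a numeric array of dim
#'   (N, C, T, V, M).
#' @return numeric matrix (N, num_classes); rows sum to 1.
#' @export
predict_proba <- function(model, batch) {
  stopifnot(inherits(model, "msstgcn_model"))
  xb <- .as_engine_batch(batch)
  t(.model_fwd(model, xb, training = FALSE)$probs)
}

#' @export
predict.msstgcn_model <- function(object, newdata, ...) {
  p <- predict_proba(object, newdata)
  max.col(p, ties.method = "first")
}

# accept (N,C,T,V,M) arrays or skeleton_datasets; return (C,T,V,M,N)
.as_engine_batch <- function(batch) {
  if (inherits(batch, "skeleton_dataset")) batch <- as_batch_array(batch)
  if (inherits(batch, "skeleton_sequence")) {
    batch <- array(batch$data, c(1L, dim(batch$data)))
  }
  d <- dim(batch)
  if (length(d) != 5L) {
    stop("batch must be a 5-D (N, C, T, V, M) array or a skeleton_dataset")
  }
  aperm(batch, c(2L, 3L, 4L, 5L, 1L))
}

#' Linear weighted fusion of two score streams
#'
#' Convex combination `alpha * u_g + (1 - alpha) * u_h` of two models'
#' class-probability matrices — the score-level fusion of the joint stream
#' and the bone stream. Rows of the result remain probability vectors.
#'
#' @param u_g,u_h numeric (N, K) matrices of class probabilities (rows sum
#'   to 1).
#' @param alpha fusion weight in \[0, 1\] (default 0.6, the empirically best
#'   setting).
#' @return numeric (N, K) probability matrix.
#' @export
fuse_scores <- function(u_g, u_h, alpha = 0.6) {
  u_g <- as.matrix(u_g)
  u_h <- as.matrix(u_h)
  if (!all(dim(u_g) == dim(u_h))) {
    stop("u_g and u_h must have the same shape")
  }
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  .check_prob_rows(u_g, "u_g")
  .check_prob_rows(u_h, "u_h")
  alpha * u_g + (1 - alpha) * u_h
}

.check_prob_rows <- function(u, name) {
  if (any(u < -1e-9) || any(abs(rowSums(u) - 1) > 1e-6)) {
    stop(name, " rows must be probability vectors (non-negative, sum 1)")
  }
  invisible(TRUE)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars: channel transforms, edge-importance
#' masks, temporal filters and biases, batch-normalization affine
#' parameters, residual projections and the final linear layer. Running
#' batch-norm statistics are not trainable and are excluded. Deterministic
#' for a fixed [model_config()].
#'
#' @param model an `msstgcn_model`.
#' @return integer scalar.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "msstgcn_model"))
  as.integer(.tree_sum(.trainable(model), length))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.msstgcn_model <- function(x, ...) {
  rows <- list(tibble::tibble(component = "data_bn", block = NA_integer_,
                              parameters = 2L * length(x$data_bn$gamma)))
  for (i in seq_along(x$blocks)) {
    b <- x$blocks[[i]]
    n_sgc <- sum(vapply(b$sgc$theta, length, 0L)) +
      sum(vapply(b$sgc$masks, length, 0L)) + length(b$sgc$bias)
    n_tcn <- sum(vapply(b$tcn, function(br) length(br$w) + length(br$b), 0L))
    n_bn <- 2L * (length(b$bn1$gamma) + length(b$bn2$gamma))
    n_res <- if (is.null(b$res)) 0L else length(b$res$w)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      component = c("spatial_gcn", "ms_tcn", "batch_norm", "residual"),
      block = i,
      parameters = c(n_sgc, n_tcn, n_bn, n_res)
    )
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    component = "fc", block = NA_integer_,
    parameters = length(x$fc$w) + length(x$fc$b))
  dplyr::filter(dplyr::bind_rows(rows), .data$parameters > 0L)
}

#' @export
glance.msstgcn_model <- function(x, ...) {
  tibble::tibble(
    num_layers = x$config$num_layers,
    num_classes = x$config$num_classes,
    gamma = x$config$gamma,
    temporal_mode = x$config$temporal_mode,
    layout = x$layout$name,
    parameters = count_parameters(x)
  )
}
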