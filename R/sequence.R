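#' Skeleton sequence container
#'
#' One sample: a numeric array of shape (C, T, V, M) — channels, frames,
#' joints, persons — with named channels, an optional integer class label and
#' a free-form metadata list. Spatial channels are named `"x"`, `"y"`, `"z"`;
#' a detector confidence channel is named `"conf"` and must lie in [0, 1].
#' Missing detections (absent persons or dropped joints) are exact zeros
#' across all channels.
#'
#' @param data numeric array, dim (C, T, V, M).
#' @param channels character vector of C channel names; defaults to
#'   `c("x","y","conf")` for C = 3 arrays (2-D pose-estimator output) and
#'   `c("x","y","z","conf")` for C = 4.
#' @param label optional integer class label (1-based) or `NULL`.
#' @param meta optional list of metadata (e.g. source identifier).
#' @return A `skeleton_sequence` object.
#' @export
skeleton_sequence <- function(data, channels = NULL, label = NULL,
                              meta = list()) {
  data <- as.array(data)
  if (length(dim(data)) != 4L) {
    stop("data must be a 4-D array (channels, frames, joints, persons)")
  }
  if (any(!is.finite(data))) stop("data contains NaN/Inf")
  c_n <- dim(data)[1L]
  if (is.null(channels)) {
    channels <- switch(as.character(c_n),
      "2" = c("x", "y"),
      "3" = c("x", "y", "conf"),
      "4" = c("x", "y", "z", "conf"),
      stop("cannot infer channel names for C = ", c_n,
           "; pass `channels` explicitly"))
  }
  if (length(channels) != c_n) {
    stop("channels has length ", length(channels), " but data has ", c_n,
         " channels")
  }
  ci <- match("conf", channels)
  if (!is.na(ci)) {
    conf <- data[ci, , , ]
    if (any(conf < 0 | conf > 1)) {
      stop("confidence channel must lie in [0, 1]")
    }
  }
  structure(
    list(data = data, channels = channels,
         label = if (is.null(label)) NULL else as.integer(label),
         meta = meta),
    class = "skeleton_sequence"
  )
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  d <- dim(x$data)
  cat("<skeleton_sequence> C=", d[1L], " (", paste(x$channels, collapse = ","),
      "), T=", d[2L], ", V=", d[3L], ", M=", d[4L],
      if (!is.null(x$label)) paste0(", label=", x$label) else "",
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.skeleton_sequence <- function(x) dim(x$data)

# indices of the spatial coordinate channels ("x","y","z")
.spatial_channels <- function(seq) {
  which(seq$channels %in% c("x", "y", "z"))
}

#' Labelled dataset of skeleton sequences
#'
#' A homogeneous collection of [skeleton_sequence()] samples sharing one
#' layout and channel set, plus 1-based integer labels.
#'
#' @param sequences list of `skeleton_sequence` objects with identical
#'   dimensions and channels.
#' @param labels integer vector of 1-based class labels, one per sequence
#'   (defaults to each sequence's own `label`).
#' @param layout_name name of the skeleton layout the joints refer to.
#' @return A `skeleton_dataset` object.
#' @export
skeleton_dataset <- function(sequences, labels = NULL, layout_name) {
  stopifnot(length(sequences) > 0L)
  dims <- vapply(sequences, function(s) dim(s$data), integer(4L))
  if (any(dims != dims[, 1L])) {
    stop("all sequences in a dataset must share the same (C, T, V, M) shape")
  }
  if (is.null(labels)) {
    labels <- vapply(sequences, function(s) {
      if (is.null(s$label)) NA_integer_ else s$label
    }, integer(1L))
  }
  labels <- as.integer(labels)
  if (length(labels) != length(sequences)) {
    stop("labels must have one entry per sequence")
  }
  structure(
    list(sequences = sequences, labels = labels, layout_name = layout_name,
         channels = sequences[[1L]]$channels),
    class = "skeleton_dataset"
  )
}

#' @export
length.skeleton_dataset <- function(x) length(x$sequences)

#' @export
print.skeleton_dataset <- function(x, ...) {
  d <- dim(x$sequences[[1L]]$data)
  cat("<skeleton_dataset> ", length(x$sequences), " sequences (C=", d[1L],
      ", T=", d[2L], ", V=", d[3L], ", M=", d[4L], "), layout ",
      x$layout_name, ", ", length(unique(x$labels[!is.na(x$labels)])),
      " classes\n", sep = "")
  invisible(x)
}

#' Stack a dataset into a batch array
#'
#' @param dataset a `skeleton_dataset`.
#' @return numeric array of dim (N, C, T, V, M).
#' @export
as_batch_array <- function(dataset) {
  stopifnot(inherits(dataset, "skeleton_dataset"))
  d <- dim(dataset$sequences[[1L]]$data)
  n <- length(dataset$sequences)
  out <- array(0, c(n, d))
  for (i in seq_len(n)) out[i, , , , ] <- dataset$sequences[[i]]$data
  out
}

#' Stratified train/test split of a skeleton dataset
#'
#' @param dataset a `skeleton_dataset` with labels.
#' @param n_test_per_class held-out sequences per class.
#' @param seed integer seed controlling the (stratified) sampling.
#' @return list with `train` and `test` datasets.
#' @export
split_dataset <- function(dataset, n_test_per_class, seed = 1L) {
  stopifnot(inherits(dataset, "skeleton_dataset"))
  labs <- dataset$labels
  if (anyNA(labs)) stop("split_dataset requires labelled sequences")
  test_idx <- integer(0)
  withr_seed <- .local_seed(seed)
  on.exit(withr_seed(), add = TRUE)
  for (k in sort(unique(labs))) {
    idx <- which(labs == k)
    if (length(idx) <= n_test_per_class) {
      stop("class ", k, " has only ", length(idx), " sequences; cannot hold ",
           n_test_per_class, " out")
    }
    test_idx <- c(test_idx, sample(idx, n_test_per_class))
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(labs), test_idx)
  list(
    train = skeleton_dataset(dataset$sequences[train_idx], labs[train_idx],
                             dataset$layout_name),
    test = skeleton_dataset(dataset$sequences[test_idx], labs[test_idx],
                            dataset$layout_name)
  )
}

# Temporarily reseed the session RNG; returns a restorer function.
.local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
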