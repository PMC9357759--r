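#' Training configuration
#'
#' Optimization settings for [train_msstgcn()]. Two named profiles are
#' provided: `"table1"` holds the full-scale reference settings (SGD with momentum
#' 0.9, learning rate 0.001, batch size 10, 150 epochs, rotation
#' augmentation on), and `"quick"` is the desk-scale profile used throughout
#' the package's own experiments (30 epochs, learning rate 0.01, no
#' augmentation, early stopping once validation accuracy saturates). Any
#' field can be overridden through `...`.
#'
#' @param profile `"quick"` (default) or `"table1"`.
#' @param ... named overrides of any field below.
#' @return A `train_config` list with fields `learning_rate`, `batch_size`,
#'   `epochs`, `momentum`, `weight_decay`, `seed`, `augment`, `max_degrees`,
#'   `val_frac`, `early_stop_target`, `early_stop_patience`, `verbose`.
#' @export
train_config <- function(profile = c("quick", "table1"), ...) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    table1 = list(learning_rate = 0.001, batch_size = 10L, epochs = 150L,
                  momentum = 0.9, weight_decay = 0, seed = 1L,
                  augment = TRUE, max_degrees = 18, val_frac = 0.1,
                  early_stop_target = Inf, early_stop_patience = 2L,
                  verbose = FALSE),
    quick = list(learning_rate = 0.01, batch_size = 10L, epochs = 30L,
                 momentum = 0.9, weight_decay = 0, seed = 1L,
                 augment = FALSE, max_degrees = 18, val_frac = 0.15,
                 early_stop_target = 1.0, early_stop_patience = 2L,
                 verbose = FALSE)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown train_config fields: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  cfg$profile <- profile
  structure(cfg, class = "train_config")
}

#' Train an MS-ST-GCN classifier
#'
#' Minibatch SGD with momentum on the cross-entropy loss. Optionally applies
#' random 3-D rotation augmentation to every training sequence each epoch.
#' A stratified validation split is carved from the training data (fraction
#' `val_frac`) unless an explicit `validation` dataset is given; the
#' parameters with the best validation accuracy are kept (checkpointing),
#' and training stops early once validation accuracy reaches
#' `early_stop_target` for `early_stop_patience` consecutive epochs. The
#' whole run is deterministic for a fixed `config$seed` (single-threaded).
#'
#' @param model an untrained (or warm) `msstgcn_model`.
#' @param dataset a labelled `skeleton_dataset`.
#' @param config a [train_config()].
#' @param validation optional held-out `skeleton_dataset` for validation.
#' @return An `msstgcn_fit`: list with `model` (best-validation parameters),
#'   `history` (one tibble row per completed epoch: `epoch`, `train_loss`,
#'   `train_accuracy`, `val_accuracy`, `learning_rate`, `seconds`) and
#'   `config`.
#' @export
train_msstgcn <- function(model, dataset, config = train_config(),
                          validation = NULL) {
  stopifnot(inherits(model, "msstgcn_model"),
            inherits(dataset, "skeleton_dataset"))
  if (length(dataset) == 0L) stop("empty dataset")
  labs <- dataset$labels
  if (anyNA(labs)) stop("training requires labelled sequences")
  k <- model$config$num_classes
  if (any(labs < 1L | labs > k)) {
    stop("labels must lie in [1, num_classes = ", k, "]")
  }
  restore <- .local_seed(config$seed)
  on.exit(restore(), add = TRUE)

  if (is.null(validation) && config$val_frac > 0) {
    n_val <- max(1L, floor(config$val_frac * length(dataset) /
                             length(unique(labs))))
    parts <- split_dataset(dataset, n_val, seed = config$seed)
    dataset <- parts$train
    validation <- parts$test
    labs <- dataset$labels
  }

  xb <- .as_engine_batch(dataset)            # (C, T, V, M, N)
  d <- dim(xb)
  n <- d[5L]
  sp <- which(dataset$channels %in% c("x", "y", "z"))
  xval <- if (!is.null(validation)) .as_engine_batch(validation) else NULL

  history <- list()
  best <- list(val = -Inf, model = model)
  streak <- 0L
  for (epoch in seq_len(config$epochs)) {
    t0 <- proc.time()[["elapsed"]]
    idx <- sample.int(n)
    xe <- xb
    if (isTRUE(config$augment)) {
      for (i in seq_len(n)) {
        theta <- stats::runif(3L, -config$max_degrees, config$max_degrees) *
          pi / 180
        if (length(sp) == 2L) theta[1:2] <- 0
        xe[, , , , i] <- .rotate_spatial(
          array(xe[, , , , i], d[1:4]), sp, theta)
      }
    }
    epoch_loss <- 0
    epoch_hits <- 0L
    velocity <- if (epoch == 1L) .tree_map(.trainable(model), function(p) 0 * p)
                else velocity
    starts <- seq(1L, n, by = config$batch_size)
    for (s in starts) {
      take <- idx[s:min(s + config$batch_size - 1L, n)]
      fw <- .model_fwd(model, xe[, , , , take, drop = FALSE],
                       training = TRUE, dropout = model$config$dropout)
      y <- labs[take]
      nb <- length(take)
      picked <- fw$probs[cbind(y, seq_len(nb))]
      epoch_loss <- epoch_loss - sum(log(pmax(picked, 1e-12)))
      epoch_hits <- epoch_hits + sum(max.col(t(fw$probs)) == y)
      dlogits <- fw$probs
      dlogits[cbind(y, seq_len(nb))] <-
        dlogits[cbind(y, seq_len(nb))] - 1
      dlogits <- dlogits / nb
      bw <- .model_bwd(model, fw$cache, dlogits)
      step <- .sgd_step(.trainable(model), bw$grads, velocity,
                        config$learning_rate, config$momentum,
                        config$weight_decay)
      velocity <- step$velocity
      model <- .restore_params(model, step$params)
      model <- .model_track(model, fw$stats)
    }
    val_acc <- NA_real_
    if (!is.null(xval)) {
      pv <- t(.model_fwd(model, xval, training = FALSE)$probs)
      val_acc <- mean(max.col(pv, ties.method = "first") ==
                        validation$labels)
      if (val_acc > best$val) {
        best$val <- val_acc
        best$model <- model
      }
      streak <- if (val_acc >= config$early_stop_target) streak + 1L else 0L
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_loss = epoch_loss / n,
      train_accuracy = epoch_hits / n,
      val_accuracy = val_acc,
      learning_rate = config$learning_rate,
      seconds = proc.time()[["elapsed"]] - t0
    )
    if (isTRUE(config$verbose)) {
      message(sprintf("epoch %3d  loss %.4f  train %.3f  val %s", epoch,
                      epoch_loss / n, epoch_hits / n,
                      ifelse(is.na(val_acc), "-", sprintf("%.3f", val_acc))))
    }
    if (streak >= config$early_stop_patience) break
  }
  final <- if (!is.null(xval) && best$val > -Inf) best$model else model
  structure(
    list(model = final, history = dplyr::bind_rows(history),
         config = config),
    class = "msstgcn_fit"
  )
}

#' @export
print.msstgcn_fit <- function(x, ...) {
  h <- x$history
  cat("<msstgcn_fit> ", nrow(h), " epochs; final train loss ",
      sprintf("%.4f", h$train_loss[nrow(h)]),
      if (!all(is.na(h$val_accuracy)))
        paste0("; best val accuracy ",
               sprintf("%.3f", max(h$val_accuracy, na.rm = TRUE))) else "",
      "\n", sep = "")
  invisible(x)
}

#' Top-k accuracy
#'
#' Fraction of samples whose true label is among the k highest-probability
#' classes, for each k in `ks`. Non-decreasing in k, and exactly 1 when
#' `k >= num_classes`. Rank ties are broken by class index (stable order).
#'
#' @param model an `msstgcn_model` or `msstgcn_fit` (alternatively pass a
#'   probability matrix via `probs`).
#' @param dataset a labelled `skeleton_dataset`.
#' @param ks integer vector of cutoffs (ascending; all >= 1).
#' @param probs optional precomputed (N, K) probability matrix; when given,
#'   `model` may be `NULL`.
#' @return tibble with columns `k`, `accuracy`, `n`.
#' @export
evaluate_topk <- function(model, dataset, ks = c(1L, 2L, 6L), probs = NULL) {
  ks <- as.integer(ks)
  if (any(ks < 1L)) stop("all ks must be >= 1")
  if (is.unsorted(ks)) stop("ks must be sorted ascending")
  if (inherits(model, "msstgcn_fit")) model <- model$model
  if (is.null(probs)) probs <- predict_proba(model, dataset)
  labels <- dataset$labels
  n <- nrow(probs)
  kc <- ncol(probs)
  ranks <- integer(n)
  for (i in seq_len(n)) {
    ord <- order(-probs[i, ], seq_len(kc))
    ranks[i] <- which(ord == labels[i])
  }
  tibble::tibble(
    k = ks,
    accuracy = vapply(ks, function(kk) mean(ranks <= kk), 0),
    n = n
  )
}

#' @export
tidy.msstgcn_fit <- function(x, ...) x$history

#' @export
glance.msstgcn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    final_train_loss = h$train_loss[nrow(h)],
    final_train_accuracy = h$train_accuracy[nrow(h)],
    best_val_accuracy = if (all(is.na(h$val_accuracy))) NA_real_
                        else max(h$val_accuracy, na.rm = TRUE),
    parameters = count_parameters(x$model)
  )
}
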