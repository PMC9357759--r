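# Internal CPU tensor engine: forward and backward passes for every layer of
# the MS-ST-GCN. Activations are numeric arrays shaped (C, V, U, T) — channel,
# joint, folded person-by-batch index U = M*N, frame — so that a temporal
# shift is a pure column offset of the flattened (C, V*U*T) matrix view; the
# temporal convolutions then run as one BLAS dgemm per kernel tap in C++
# (src/conv.cpp) with no data rearrangement. Each *_fwd returns
# list(y, cache [, stats]); each *_bwd consumes the cache and returns the
# input gradient plus per-parameter gradients in the same nested shape the
# parameters have, so the SGD update can walk both trees in parallel.

.he_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

# ---- batch normalization -----------------------------------------------

.bn_init <- function(c_n) {
  list(gamma = rep(1, c_n), beta = rep(0, c_n),
       mean = rep(0, c_n), var = rep(1, c_n))
}

# x: (C x m) matrix view; per-row (channel) statistics over columns.
.bn_fwd <- function(x, bn, training, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(x)
    xc <- x - mu
    v <- rowMeans(xc * xc)
  } else {
    mu <- bn$mean
    v <- bn$var
    xc <- x - mu
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- xhat * bn$gamma + bn$beta
  list(y = y,
       cache = list(xhat = xhat, inv = inv, gamma = bn$gamma, m = ncol(x)),
       stats = if (training) list(mean = mu, var = v) else NULL)
}

.bn_bwd <- function(dy, cache) {
  xhat <- cache$xhat
  m <- cache$m
  dgamma <- rowSums(dy * xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  dx <- (cache$inv / m) *
    (m * dxhat - rowSums(dxhat) - xhat * rowSums(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# exponential-moving-average update of running statistics
.bn_track <- function(bn, stats, momentum = 0.1) {
  bn$mean <- (1 - momentum) * bn$mean + momentum * stats$mean
  bn$var <- (1 - momentum) * bn$var + momentum * stats$var
  bn
}

# ---- subset-wise spatial graph convolution ------------------------------
# y[c_out, x, u, t] = bias + sum_z Theta_z (sum_y (S_z * mask_z)[x, y] f[c, y, u, t])

.sgc_fwd <- function(x, subsets, theta, masks, bias) {
  d <- dim(x)
  c_in <- d[1L]; v <- d[2L]; u <- d[3L]; t_n <- d[4L]
  c_out <- nrow(theta[[1L]])
  xp <- aperm(x, c(2L, 1L, 3L, 4L))
  dim(xp) <- c(v, c_in * u * t_n)
  ymat <- matrix(0, c_out, v * u * t_n)
  hs <- vector("list", length(subsets))
  for (z in seq_along(subsets)) {
    az <- subsets[[z]] * masks[[z]]
    hz <- az %*% xp                       # (V, C*U*T)
    dim(hz) <- c(v, c_in, u, t_n)
    hz <- aperm(hz, c(2L, 1L, 3L, 4L))    # (C, V, U, T)
    dim(hz) <- c(c_in, v * u * t_n)
    hs[[z]] <- hz
    ymat <- ymat + theta[[z]] %*% hz
  }
  ymat <- ymat + bias
  dim(ymat) <- c(c_out, v, u, t_n)
  list(y = ymat, cache = list(xp = xp, hs = hs, dims = d,
                              subsets = subsets, theta = theta,
                              masks = masks))
}

.sgc_bwd <- function(dy, cache) {
  d <- cache$dims
  c_in <- d[1L]; v <- d[2L]; u <- d[3L]; t_n <- d[4L]
  c_out <- dim(dy)[1L]
  dym <- dy
  dim(dym) <- c(c_out, v * u * t_n)
  dtheta <- vector("list", length(cache$subsets))
  dmasks <- vector("list", length(cache$subsets))
  dxp <- matrix(0, v, c_in * u * t_n)
  for (z in seq_along(cache$subsets)) {
    dtheta[[z]] <- tcrossprod(dym, cache$hs[[z]])      # (Cout, Cin)
    dh <- crossprod(cache$theta[[z]], dym)             # (Cin, V*U*T)
    dim(dh) <- c(c_in, v, u, t_n)
    dh <- aperm(dh, c(2L, 1L, 3L, 4L))                 # (V, C, U, T)
    dim(dh) <- c(v, c_in * u * t_n)
    da <- tcrossprod(dh, cache$xp)                     # (V, V)
    dmasks[[z]] <- da * cache$subsets[[z]]
    az <- cache$subsets[[z]] * cache$masks[[z]]
    dxp <- dxp + crossprod(az, dh)
  }
  dbias <- rowSums(dym)
  dim(dxp) <- c(v, c_in, u, t_n)
  dx <- aperm(dxp, c(2L, 1L, 3L, 4L))
  list(dx = dx, dtheta = dtheta, dmasks = dmasks, dbias = dbias)
}

# ---- temporal convolution ----------------------------------------------
# 1-D convolution along the frame axis, same-padded with
# left = ceil((k-1)/2), right = floor((k-1)/2); optional output stride.

.tconv_fwd <- function(x, w, b, stride = 1L) {
  d <- dim(x)
  c_in <- d[1L]; vn <- d[2L] * d[3L]; t_n <- d[4L]
  c_out <- dim(w)[1L]
  k <- dim(w)[3L]
  left <- as.integer(ceiling((k - 1L) / 2))
  y <- .cpp_tconv_fwd(x, w, b, c_in, vn, t_n, c_out, k, left)
  dim(y) <- c(c_out, d[2L], d[3L], t_n)
  if (stride > 1L) {
    t_keep <- seq(1L, t_n, by = stride)
    y <- y[, , , t_keep, drop = FALSE]
  }
  list(y = y, cache = list(x = x, dims = d, k = k, left = left,
                           stride = stride, c_out = c_out))
}

.tconv_bwd <- function(dy, w, cache) {
  d <- cache$dims
  c_in <- d[1L]; vn <- d[2L] * d[3L]; t_n <- d[4L]
  c_out <- cache$c_out
  if (cache$stride > 1L) {
    dyf <- array(0, c(c_out, d[2L], d[3L], t_n))
    t_keep <- seq(1L, t_n, by = cache$stride)
    dyf[, , , t_keep] <- dy
  } else {
    dyf <- dy
  }
  dx <- .cpp_tconv_bwd_dx(dyf, w, c_in, vn, t_n, c_out, cache$k,
                          cache$left)
  dw <- .cpp_tconv_bwd_dw(dyf, cache$x, c_in, vn, t_n, c_out, cache$k,
                          cache$left)
  dim(dw) <- dim(w)
  db <- rowSums(matrix(dyf, c_out))
  dim(dx) <- d
  list(dx = dx, dw = dw, db = db)
}

# ---- ReLU ---------------------------------------------------------------

.relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

.relu_bwd <- function(dy, mask) {
  dy * mask
}

# ---- one ST-GCN block ---------------------------------------------------
# spatial graph conv -> BN -> ReLU -> multiscale temporal conv -> BN,
# plus the temporal-level residual (the block's own post-spatial features)
# and the block-level residual (identity or strided 1x1), then ReLU.

.block_init <- function(c_in, c_out, v, gamma, stride, mode) {
  if (c_out %% 2L != 0L) stop("block output channels must be even")
  if (gamma < 1L) stop("gamma must be >= 1")
  branches <- if (identical(mode, "single")) {
    list(list(w = .he_init(c_out * gamma, c(c_out, c_out, gamma)),
              b = rep(0, c_out)))
  } else {
    half <- c_out %/% 2L
    list(list(w = .he_init(c_out * gamma, c(half, c_out, gamma)),
              b = rep(0, half)),
         list(w = .he_init(c_out * 2L * gamma, c(half, c_out, 2L * gamma)),
              b = rep(0, half)))
  }
  list(
    c_in = c_in, c_out = c_out, gamma = as.integer(gamma),
    stride = as.integer(stride), mode = mode,
    sgc = list(
      theta = lapply(1:3, function(z) .he_init(c_in, c(c_out, c_in))),
      masks = lapply(1:3, function(z) matrix(1, v, v)),
      bias = rep(0, c_out)
    ),
    bn1 = .bn_init(c_out),
    tcn = branches,
    bn2 = .bn_init(c_out),
    res = if (c_in != c_out) list(w = .he_init(c_in, c(c_out, c_in)))
          else NULL
  )
}

.block_fwd <- function(x, block, subsets, training) {
  d_in <- dim(x)
  sg <- .sgc_fwd(x, subsets, block$sgc$theta, block$sgc$masks, block$sgc$bias)
  s_dims <- dim(sg$y)
  b1 <- .bn_fwd(matrix(sg$y, s_dims[1L]), block$bn1, training)
  r1 <- .relu_fwd(b1$y)
  h <- array(r1$y, s_dims)
  tc <- lapply(block$tcn, function(br)
    .tconv_fwd(h, br$w, br$b, block$stride))
  tcat <- if (length(tc) == 1L) tc[[1L]]$y else {
    yd <- dim(tc[[1L]]$y)
    out <- array(0, c(block$c_out, yd[2L], yd[3L], yd[4L]))
    out[seq_len(yd[1L]), , , ] <- tc[[1L]]$y
    out[yd[1L] + seq_len(dim(tc[[2L]]$y)[1L]), , , ] <- tc[[2L]]$y
    out
  }
  t_dims <- dim(tcat)
  b2 <- .bn_fwd(matrix(tcat, t_dims[1L]), block$bn2, training)
  # temporal residual: post-spatial features, strided to match
  t_keep <- seq(1L, s_dims[4L], by = block$stride)
  hres <- h[, , , t_keep, drop = FALSE]
  # block residual: input, strided (and 1x1-projected when widths differ)
  if (is.null(block$res)) {
    xres <- x[, , , t_keep, drop = FALSE]
    res_cache <- NULL
  } else {
    xs <- x[, , , t_keep, drop = FALSE]
    xs_mat <- matrix(xs, d_in[1L])
    xres <- array(block$res$w %*% xs_mat, t_dims)
    res_cache <- xs_mat
  }
  pre <- array(b2$y, t_dims) + hres + xres
  r2 <- .relu_fwd(pre)
  list(y = r2$y,
       cache = list(sg = sg$cache, b1 = b1$cache, r1 = r1$cache,
                    tc = lapply(tc, `[[`, "cache"), b2 = b2$cache,
                    r2 = r2$cache, s_dims = s_dims, t_dims = t_dims,
                    d_in = d_in, t_keep = t_keep, res_cache = res_cache),
       stats = list(bn1 = b1$stats, bn2 = b2$stats))
}

.block_bwd <- function(dy, block, cache) {
  t_dims <- cache$t_dims
  s_dims <- cache$s_dims
  d_in <- cache$d_in
  dpre <- .relu_bwd(dy, cache$r2)
  # split into BN2 path, temporal residual, block residual
  db2 <- .bn_bwd(matrix(dpre, t_dims[1L]), cache$b2)
  dtcat <- array(db2$dx, t_dims)
  dh <- array(0, s_dims)
  dh[, , , cache$t_keep] <- dh[, , , cache$t_keep] + dpre
  dx <- array(0, d_in)
  dres <- NULL
  if (is.null(block$res)) {
    dx[, , , cache$t_keep] <- dx[, , , cache$t_keep] + dpre
  } else {
    dpre_mat <- matrix(dpre, t_dims[1L])
    dres <- list(w = tcrossprod(dpre_mat, cache$res_cache))
    dxs <- crossprod(block$res$w, dpre_mat)
    dim(dxs) <- c(d_in[1L], d_in[2L], d_in[3L], length(cache$t_keep))
    dx[, , , cache$t_keep] <- dx[, , , cache$t_keep] + dxs
  }
  # temporal branches
  dtcn <- vector("list", length(block$tcn))
  offset <- 0L
  for (i in seq_along(block$tcn)) {
    ci <- dim(block$tcn[[i]]$w)[1L]
    dyb <- dtcat[offset + seq_len(ci), , , , drop = FALSE]
    tb <- .tconv_bwd(dyb, block$tcn[[i]]$w, cache$tc[[i]])
    dtcn[[i]] <- list(w = tb$dw, b = tb$db)
    dh <- dh + tb$dx
    offset <- offset + ci
  }
  # back through ReLU -> BN1 -> spatial conv
  dr1 <- .relu_bwd(matrix(dh, s_dims[1L]), cache$r1)
  db1 <- .bn_bwd(dr1, cache$b1)
  dsg <- .sgc_bwd(array(db1$dx, s_dims), cache$sg)
  dx <- dx + dsg$dx
  grads <- list(
    sgc = list(theta = dsg$dtheta, masks = dsg$dmasks, bias = dsg$dbias),
    bn1 = list(gamma = db1$dgamma, beta = db1$dbeta),
    tcn = dtcn,
    bn2 = list(gamma = db2$dgamma, beta = db2$dbeta)
  )
  if (!is.null(dres)) grads$res <- dres
  list(dx = dx, grads = grads)
}

# ---- full network -------------------------------------------------------

.model_fwd <- function(model, xb, training = FALSE, dropout = 0) {
  d <- dim(xb)                               # (C, T, V, M, N)
  c_n <- d[1L]; t_n <- d[2L]; v <- d[3L]; m <- d[4L]; n <- d[5L]
  if (v != nrow(model$graph$normalized)) {
    stop("batch has ", v, " joints but the model's layout has ",
         nrow(model$graph$normalized))
  }
  if (any(!is.finite(xb))) stop("non-finite values in input batch")
  if (c_n * v * m != length(model$data_bn$gamma)) {
    stop("batch channel/person shape does not match the model's input ",
         "normalization layer (built for C*V*M = ",
         length(model$data_bn$gamma), ")")
  }
  # input BN over the flattened (C, V, M) axis, statistics over frames and batch
  xp <- aperm(xb, c(1L, 3L, 4L, 2L, 5L))     # (C, V, M, T, N)
  dim(xp) <- c(c_n * v * m, t_n * n)
  dbn <- .bn_fwd(xp, model$data_bn, training)
  y <- array(dbn$y, c(c_n, v, m, t_n, n))
  y <- aperm(y, c(1L, 2L, 3L, 5L, 4L))       # (C, V, M, N, T)
  dim(y) <- c(c_n, v, m * n, t_n)            # persons folded into batch
  caches <- vector("list", length(model$blocks))
  stats <- vector("list", length(model$blocks))
  for (i in seq_along(model$blocks)) {
    bf <- .block_fwd(y, model$blocks[[i]], model$graph$subsets, training)
    y <- bf$y
    caches[[i]] <- bf$cache
    stats[[i]] <- bf$stats
  }
  yd <- dim(y)                               # (C_last, V, M*N, T')
  pooled <- matrix(0, yd[1L], yd[3L])
  for (i in seq_len(yd[3L])) {
    pooled[, i] <- rowMeans(matrix(y[, , i, ], yd[1L]))
  }
  dim(pooled) <- c(yd[1L], m, n)
  pm <- matrix(0, yd[1L], n)
  for (i in seq_len(n)) pm[, i] <- rowMeans(matrix(pooled[, , i], yd[1L]))
  drop_mask <- NULL
  if (training && dropout > 0) {
    drop_mask <- matrix((stats::runif(length(pm)) >= dropout) / (1 - dropout),
                        nrow(pm))
    pm <- pm * drop_mask
  }
  logits <- model$fc$w %*% pm + model$fc$b   # (K, N)
  lmax <- apply(logits, 2L, max)
  ex <- exp(sweep(logits, 2L, lmax))
  probs <- sweep(ex, 2L, colSums(ex), "/")
  list(probs = probs, logits = logits,
       cache = list(dbn = dbn$cache, blocks = caches, yd = yd,
                    pm = pm, drop_mask = drop_mask, m = m, n = n,
                    t_n = t_n, v = v, c_n = c_n),
       stats = list(data_bn = dbn$stats, blocks = stats))
}

.model_bwd <- function(model, cache, dlogits) {
  yd <- cache$yd
  m <- cache$m; n <- cache$n
  dfc <- list(w = tcrossprod(dlogits, cache$pm), b = rowSums(dlogits))
  dpm <- crossprod(model$fc$w, dlogits)      # (C_last, N)
  if (!is.null(cache$drop_mask)) dpm <- dpm * cache$drop_mask
  # undo person mean and global average pooling
  dpooled <- matrix(0, yd[1L], yd[3L])
  dim(dpooled) <- c(yd[1L], m, n)
  for (i in seq_len(n)) dpooled[, , i] <- dpm[, i] / m
  dim(dpooled) <- c(yd[1L], yd[3L])
  per <- yd[2L] * yd[4L]
  dy <- array(0, yd)
  for (i in seq_len(yd[3L])) dy[, , i, ] <- dpooled[, i] / per
  grads_blocks <- vector("list", length(model$blocks))
  for (i in rev(seq_along(model$blocks))) {
    bb <- .block_bwd(dy, model$blocks[[i]], cache$blocks[[i]])
    dy <- bb$dx
    grads_blocks[[i]] <- bb$grads
  }
  # back through the person fold and input BN
  c_n <- cache$c_n; t_n <- cache$t_n; v <- cache$v
  dim(dy) <- c(c_n, v, m, n, t_n)
  dyp <- aperm(dy, c(1L, 2L, 3L, 5L, 4L))    # (C, V, M, T, N)
  dim(dyp) <- c(c_n * v * m, t_n * n)
  dbn <- .bn_bwd(dyp, cache$dbn)
  list(grads = list(data_bn = list(gamma = dbn$dgamma, beta = dbn$dbeta),
                    blocks = grads_blocks, fc = dfc))
}

# fold freshly computed batch statistics into the model's running stats
.model_track <- function(model, stats, momentum = 0.1) {
  model$data_bn <- .bn_track(model$data_bn, stats$data_bn, momentum)
  for (i in seq_along(model$blocks)) {
    model$blocks[[i]]$bn1 <- .bn_track(model$blocks[[i]]$bn1,
                                       stats$blocks[[i]]$bn1, momentum)
    model$blocks[[i]]$bn2 <- .bn_track(model$blocks[[i]]$bn2,
                                       stats$blocks[[i]]$bn2, momentum)
  }
  model
}

# ---- parameter-tree helpers --------------------------------------------

.trainable <- function(model) {
  list(
    data_bn = list(gamma = model$data_bn$gamma, beta = model$data_bn$beta),
    blocks = lapply(model$blocks, function(b) {
      g <- list(
        sgc = list(theta = b$sgc$theta, masks = b$sgc$masks,
                   bias = b$sgc$bias),
        bn1 = list(gamma = b$bn1$gamma, beta = b$bn1$beta),
        tcn = lapply(b$tcn, function(br) list(w = br$w, b = br$b)),
        bn2 = list(gamma = b$bn2$gamma, beta = b$bn2$beta)
      )
      if (!is.null(b$res)) g$res <- list(w = b$res$w)
      g
    }),
    fc = list(w = model$fc$w, b = model$fc$b)
  )
}

# write a parameter tree (same shape as .trainable output) back into a model
.restore_params <- function(model, params) {
  model$data_bn$gamma <- params$data_bn$gamma
  model$data_bn$beta <- params$data_bn$beta
  for (i in seq_along(model$blocks)) {
    p <- params$blocks[[i]]
    model$blocks[[i]]$sgc$theta <- p$sgc$theta
    model$blocks[[i]]$sgc$masks <- p$sgc$masks
    model$blocks[[i]]$sgc$bias <- p$sgc$bias
    model$blocks[[i]]$bn1$gamma <- p$bn1$gamma
    model$blocks[[i]]$bn1$beta <- p$bn1$beta
    for (j in seq_along(model$blocks[[i]]$tcn)) {
      model$blocks[[i]]$tcn[[j]]$w <- p$tcn[[j]]$w
      model$blocks[[i]]$tcn[[j]]$b <- p$tcn[[j]]$b
    }
    model$blocks[[i]]$bn2$gamma <- p$bn2$gamma
    model$blocks[[i]]$bn2$beta <- p$bn2$beta
    if (!is.null(model$blocks[[i]]$res)) {
      model$blocks[[i]]$res$w <- p$res$w
    }
  }
  model$fc$w <- params$fc$w
  model$fc$b <- params$fc$b
  model
}

.tree_map <- function(x, f) {
  if (is.list(x)) lapply(x, .tree_map, f = f) else f(x)
}

.tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a)) out[[i]] <- .tree_map2(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

.tree_sum <- function(x, f) {
  if (is.list(x)) sum(vapply(x, .tree_sum, 0, f = f)) else f(x)
}

# one SGD-with-momentum step; returns list(params, velocity)
.sgd_step <- function(params, grads, velocity, lr, momentum,
                      weight_decay = 0) {
  velocity <- .tree_map2(velocity, .tree_map2(grads, params, function(g, p) {
    if (weight_decay > 0) g + weight_decay * p else g
  }), function(v, g) momentum * v + g)
  params <- .tree_map2(params, velocity, function(p, v) p - lr * v)
  list(params = params, velocity = velocity)
}
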