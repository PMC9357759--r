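test_that("identity aggregation: self-loop-only graph with unit transforms", {
  lay <- isolated1_layout()
  g <- graph_tensors(lay)
  params <- layer_parameters(2L, 2L, 1L, gamma = 2L, seed = 1)
  params$sgc$theta <- list(diag(2), diag(2), diag(2))
  params$sgc$bias <- c(0, 0)
  x <- array(stats::rnorm(2L * 7L * 1L), c(2L, 7L, 1L))
  expect_equal(spatial_graph_conv(x, g, params), x, tolerance = 1e-12)
})

test_that("spatial graph convolution equals the per-node neighborhood sum", {
  for (trial in 1:25) {
    v <- 2L + (trial %% 9L)
    lay <- random_tree_layout(v, seed = 100 + trial)
    g <- graph_tensors(lay)
    set.seed(200 + trial)
    c_in <- sample(1:3, 1)
    c_out <- sample(1:4, 1)
    params <- layer_parameters(c_in, 4L, v, gamma = 2L, seed = trial)
    params$sgc$theta <- lapply(1:3, function(z) matrix(rnorm(c_out * c_in),
                                                      c_out, c_in))
    params$sgc$masks <- lapply(1:3, function(z) matrix(runif(v * v), v, v))
    params$sgc$bias <- rnorm(c_out)
    x <- array(rnorm(c_in * 4L * v), c(c_in, 4L, v))
    expect_equal(spatial_graph_conv(x, g, params),
                 sgc_node_oracle(x, g, params), tolerance = 1e-5)
  }
})

test_that("spatial graph convolution is equivariant to joint relabeling", {
  lay <- random_tree_layout(8L, seed = 7)
  g <- graph_tensors(lay)
  set.seed(8)
  perm <- sample.int(8L)
  inv <- order(perm)
  lay_p <- new_skeleton_layout("perm", lay$joint_names[inv],
                               matrix(perm[lay$edges], ncol = 2L),
                               lay$template_pose[inv, ],
                               perm[lay$center_joint])
  gp <- graph_tensors(lay_p)
  params <- layer_parameters(2L, 2L, 8L, gamma = 2L, seed = 3)
  params_p <- params
  params_p$sgc$masks <- lapply(params$sgc$masks, function(m) m[inv, inv])
  x <- array(rnorm(2L * 5L * 8L), c(2L, 5L, 8L))
  y <- spatial_graph_conv(x, g, params)
  yp <- spatial_graph_conv(x[, , inv, drop = FALSE], gp, params_p)
  expect_equal(yp, y[, , inv, drop = FALSE], tolerance = 1e-10)
})

test_that("zeroing an edge mask makes the root invariant to that neighbor", {
  lay <- build_layout("synthetic20")
  g <- graph_tensors(lay)
  params <- layer_parameters(3L, 4L, 20L, gamma = 2L, seed = 5)
  x1 <- array(stats::rnorm(3L * 6L * 20L), c(3L, 6L, 20L))
  root <- 1L
  nbr <- 2L                                  # pelvis-spine bone
  for (z in 1:3) params$sgc$masks[[z]][root, nbr] <- 0
  x2 <- x1
  x2[, , nbr] <- x2[, , nbr] + stats::rnorm(3L * 6L)
  y1 <- spatial_graph_conv(x1, g, params)
  y2 <- spatial_graph_conv(x2, g, params)
  expect_equal(y2[, , root], y1[, , root], tolerance = 1e-10)
  expect_gt(max(abs(y2 - y1)), 1e-3)         # other joints do change
})

test_that("zero-filter multiscale temporal convolution is the identity", {
  params <- layer_parameters(4L, 4L, 5L, gamma = 3L, seed = 2)
  for (br in seq_along(params$tcn)) {
    params$tcn[[br]]$w[] <- 0
    params$tcn[[br]]$b[] <- 0
  }
  x <- array(abs(stats::rnorm(4L * 9L * 5L)), c(4L, 9L, 5L))  # non-negative
  expect_equal(ms_tcn(x, params), x, tolerance = 1e-9)
})

test_that("temporal convolution conserves frames for both kernel extents", {
  # gamma = 3 pairs a width-3 branch with a width-6 branch; both same-padded
  params <- layer_parameters(6L, 6L, 4L, gamma = 3L, seed = 4)
  x <- array(stats::rnorm(6L * 25L * 4L), c(6L, 25L, 4L))
  expect_identical(dim(ms_tcn(x, params)), c(6L, 25L, 4L))
  # the even 2*gamma kernel on its own, against the direct-convolution oracle
  set.seed(10)
  w <- array(rnorm(2L * 3L * 6L), c(2L, 3L, 6L))
  b <- rnorm(2L)
  x3 <- array(rnorm(3L * 11L * 2L), c(3L, 11L, 2L))
  got <- msstgcn:::.tconv_fwd(msstgcn:::.ctv_to_engine(x3), w, b)$y
  expect_equal(msstgcn:::.engine_to_ctv(got), tconv_oracle(x3, w, b),
               tolerance = 1e-10)
  # odd kernel too
  w9 <- array(rnorm(4L * 3L * 9L), c(4L, 3L, 9L))
  got9 <- msstgcn:::.tconv_fwd(msstgcn:::.ctv_to_engine(x3), w9, rep(0, 4L))$y
  expect_equal(msstgcn:::.engine_to_ctv(got9),
               tconv_oracle(x3, w9, rep(0, 4L)), tolerance = 1e-10)
})

test_that("single-scale mode reproduces a plain temporal convolution", {
  params <- layer_parameters(4L, 4L, 3L, gamma = 3L, mode = "single",
                             seed = 6)
  expect_length(params$tcn, 1L)
  expect_identical(dim(params$tcn[[1L]]$w), c(4L, 4L, 3L))
  x <- array(stats::rnorm(4L * 10L * 3L), c(4L, 10L, 3L))
  expect_identical(dim(ms_tcn(x, params)), c(4L, 10L, 3L))
})

test_that("stacked blocks keep the joint axis and honor the shape contract", {
  lay <- build_layout("synthetic20")
  g <- graph_tensors(lay)
  x <- array(stats::rnorm(4L * 12L * 20L), c(4L, 12L, 20L))
  p1 <- layer_parameters(4L, 8L, 20L, gamma = 3L, seed = 1)
  y <- stgcn_block(x, g, p1)
  expect_identical(dim(y), c(8L, 12L, 20L))
  p2 <- layer_parameters(8L, 8L, 20L, gamma = 3L, stride = 2L, seed = 2)
  y2 <- stgcn_block(y, g, p2)
  expect_identical(dim(y2), c(8L, 6L, 20L))
  # ten stacked blocks preserve V throughout
  h <- x
  c_prev <- 4L
  for (i in 1:10) {
    pp <- layer_parameters(c_prev, 8L, 20L, gamma = 3L, seed = i)
    h <- stgcn_block(h, g, pp)
    c_prev <- 8L
    expect_identical(dim(h)[3L], 20L)
  }
})

test_that("backward pass matches finite differences on a tiny network", {
  cfg <- model_config(num_classes = 3L, num_layers = 2L,
                      channel_plan = c(4L, 6L), gamma = 2L,
                      strides = c(1L, 1L), dropout = 0)
  m <- build_model(cfg, in_channels = 3L, persons = 2L, seed = 3)
  set.seed(11)
  xb <- array(stats::rnorm(3L * 6L * 20L * 2L * 2L), c(3L, 6L, 20L, 2L, 2L))
  y <- c(1L, 3L)
  loss_fn <- function(model) {
    fw <- msstgcn:::.model_fwd(model, xb, training = TRUE, dropout = 0)
    -sum(log(fw$probs[cbind(y, 1:2)])) / 2
  }
  fw <- msstgcn:::.model_fwd(m, xb, training = TRUE, dropout = 0)
  dlogits <- fw$probs
  dlogits[cbind(y, 1:2)] <- dlogits[cbind(y, 1:2)] - 1
  dlogits <- dlogits / 2
  bw <- msstgcn:::.model_bwd(m, fw$cache, dlogits)
  params <- msstgcn:::.trainable(m)
  # probe a representative parameter in every layer type
  probes <- list(
    c("blocks", "1", "sgc", "theta", "2"),
    c("blocks", "1", "sgc", "masks", "3"),
    c("blocks", "2", "tcn", "1", "w"),
    c("blocks", "2", "tcn", "2", "w"),
    c("blocks", "2", "bn2", "gamma"),
    c("blocks", "2", "res", "w"),
    c("data_bn", "beta"),
    c("fc", "w")
  )
  get_at <- function(tree, path) {
    for (p in path) {
      tree <- tree[[if (grepl("^\\d+$", p)) as.integer(p) else p]]
    }
    tree
  }
  bump <- function(tree, path, idx, delta) {
    rec <- function(t, p) {
      if (length(p) == 0L) { t[idx] <- t[idx] + delta; return(t) }
      key <- if (grepl("^\\d+$", p[1L])) as.integer(p[1L]) else p[1L]
      t[[key]] <- rec(t[[key]], p[-1L])
      t
    }
    rec(tree, path)
  }
  eps <- 1e-5
  set.seed(21)
  for (path in probes) {
    leaf <- get_at(params, path)
    i <- sample.int(length(leaf), 1L)
    lp <- loss_fn(msstgcn:::.restore_params(m, bump(params, path, i, eps)))
    lm <- loss_fn(msstgcn:::.restore_params(m, bump(params, path, i, -eps)))
    gnum <- (lp - lm) / (2 * eps)
    gana <- get_at(bw$grads, path)[i]
    expect_lt(abs(gnum - gana) / max(1e-6, abs(gnum) + abs(gana)), 1e-4)
  }
})

test_that("edge-importance masks receive gradient during training", {
  cfg <- model_config(num_classes = 2L, num_layers = 2L,
                      channel_plan = c(4L, 4L), gamma = 2L,
                      strides = c(1L, 1L), dropout = 0)
  m <- build_model(cfg, in_channels = 3L, persons = 1L, seed = 9)
  set.seed(13)
  xb <- array(stats::rnorm(3L * 8L * 20L * 1L * 4L), c(3L, 8L, 20L, 1L, 4L))
  y <- c(1L, 2L, 1L, 2L)
  fw <- msstgcn:::.model_fwd(m, xb, training = TRUE, dropout = 0)
  dlogits <- fw$probs
  dlogits[cbind(y, 1:4)] <- dlogits[cbind(y, 1:4)] - 1
  bw <- msstgcn:::.model_bwd(m, fw$cache, dlogits / 4)
  for (b in bw$grads$blocks) {
    for (z in 1:3) {
      g <- b$sgc$masks[[z]]
      expect_true(all(is.finite(g)))
    }
  }
  total <- sum(vapply(bw$grads$blocks, function(b)
    sum(abs(unlist(b$sgc$masks))), 0))
  expect_gt(total, 0)
})
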