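# Shared fixtures and independent oracles, all built in code.

# three collinear joints on a path 1-2-3; centroid sits on joint 2
collinear3_layout <- function() {
  new_skeleton_layout(
    name = "collinear3",
    joint_names = c("a", "b", "c"),
    edges = rbind(c(1L, 2L), c(2L, 3L)),
    template_pose = cbind(c(0, 1, 2), 0, 0),
    center_joint = 2L
  )
}

# a single isolated joint (no edges); requires relaxing the tree invariant
isolated1_layout <- function() {
  new_skeleton_layout(
    name = "isolated1",
    joint_names = "solo",
    edges = matrix(integer(0), ncol = 2L),
    template_pose = cbind(0.1, 0.2, 0.3),
    center_joint = 1L,
    require_tree = FALSE
  )
}

# random tree layout on v joints with distinct random template coordinates
random_tree_layout <- function(v, seed) {
  set.seed(seed)
  edges <- if (v > 1L) {
    cbind(2:v, vapply(2:v, function(i) sample.int(i - 1L, 1L), 1L))
  } else {
    matrix(integer(0), ncol = 2L)
  }
  new_skeleton_layout(
    name = paste0("rand", v, "_", seed),
    joint_names = paste0("j", seq_len(v)),
    edges = edges,
    template_pose = matrix(stats::runif(3L * v, -1, 1), v, 3L),
    center_joint = 1L,
    require_tree = v > 1L
  )
}

# per-node brute-force oracle for the subset-wise spatial graph convolution:
# explicit loop over root joints and their labelled neighbors
sgc_node_oracle <- function(features, graph, params) {
  d <- dim(features)
  c_out <- nrow(params$sgc$theta[[1L]])
  v <- d[3L]
  out <- array(0, c(c_out, d[2L], v))
  labels <- graph$subset_labels
  for (x in seq_len(v)) {
    for (y in seq_len(v)) {
      z <- labels[x, y]
      if (z < 0L) next
      w <- graph$normalized[x, y] * params$sgc$masks[[z + 1L]][x, y]
      for (t in seq_len(d[2L])) {
        out[, t, x] <- out[, t, x] +
          (params$sgc$theta[[z + 1L]] %*% features[, t, y]) * w
      }
    }
  }
  out + params$sgc$bias
}

# direct 1-D same-padded convolution along the frame axis (naive loops)
tconv_oracle <- function(features, w, b) {
  d <- dim(features)
  c_out <- dim(w)[1L]
  k <- dim(w)[3L]
  left <- ceiling((k - 1L) / 2)
  out <- array(0, c(c_out, d[2L], d[3L]))
  for (vv in seq_len(d[3L])) {
    for (t in seq_len(d[2L])) {
      acc <- b
      for (kk in seq_len(k)) {
        t2 <- t + kk - 1L - left
        if (t2 >= 1L && t2 <= d[2L]) {
          acc <- acc + matrix(w[, , kk], nrow = c_out) %*% features[, t2, vv]
        }
      }
      out[, t, vv] <- acc
    }
  }
  out
}

# resample datasets to a fixed frame count
resample_dataset <- function(ds, target = 25L) {
  skeleton_dataset(lapply(ds$sequences, resample_frames, target = target),
                   ds$labels, ds$layout_name)
}

# small OpenPose-style JSON frame writer for I/O tests
write_openpose_frame <- function(path, candidates, field = "pose_keypoints_2d") {
  people <- lapply(candidates, function(kp) {
    stats::setNames(list(as.vector(t(kp))), field)
  })
  jsonlite::write_json(list(version = 1.3, people = people), path,
                       auto_unbox = TRUE, digits = NA)
}
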