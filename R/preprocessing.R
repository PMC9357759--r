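#' Keep the k most confident persons per frame
#'
#' Pose estimators emit a variable number of candidate skeletons per frame.
#' Following the common practice for multi-person skeleton classification,
#' each frame keeps the `k` candidates with the highest mean joint
#' confidence, placed in person slots in descending-confidence order;
#' missing candidates are zero-filled. Ties are broken by the original
#' detection index (lower index wins).
#'
#' @param detections list of frames; each frame is a (possibly empty) list of
#'   candidate skeletons, each a V x C numeric matrix whose columns follow
#'   `channels` (a `"conf"` column must be present).
#' @param k number of person slots to keep (default 2, the standard choice).
#' @param channels channel names of the candidate columns
#'   (default `c("x","y","conf")`, OpenPose 2-D output).
#' @return A [skeleton_sequence()] with dim (C, T, V, M = k).
#' @export
select_top_persons <- function(detections, k = 2L,
                               channels = c("x", "y", "conf")) {
  stopifnot(k >= 1L, length(detections) >= 1L)
  ci <- match("conf", channels)
  if (is.na(ci)) stop("channels must include a 'conf' column")
  t_n <- length(detections)
  c_n <- length(channels)
  v <- NULL
  for (fr in detections) for (cand in fr) {
    if (is.null(v)) v <- nrow(cand)
    if (nrow(cand) != v || ncol(cand) != c_n) {
      stop("all candidates must be V x ", c_n, " matrices")
    }
  }
  if (is.null(v)) stop("no candidate skeleton found in any frame; ",
                       "cannot infer the joint count")
  data <- array(0, c(c_n, t_n, v, k))
  for (t in seq_len(t_n)) {
    frame <- detections[[t]]
    if (length(frame) == 0L) next
    scores <- vapply(frame, function(cand) mean(cand[, ci]), 0)
    # stable order: ties keep the original detection index
    keep <- order(-scores, seq_along(scores))[seq_len(min(k, length(frame)))]
    for (m in seq_along(keep)) {
      data[, t, , m] <- t(frame[[keep[m]]])
    }
  }
  skeleton_sequence(data, channels = channels)
}

#' Resample a sequence to a fixed frame count
#'
#' Long sequences are uniformly subsampled with the endpoint-excluded stride
#' rule: frame indices `floor(i * T / target)` for `i = 0, ..., target - 1`
#' (0-based), which are strictly increasing whenever `T >= target`. Short
#' sequences are loop-padded by repeating frames from the start. A sequence
#' already at the target length is returned unchanged.
#'
#' @param seq a [skeleton_sequence()].
#' @param target frame count after resampling (default 25, the standard
#'   fixed skeleton-sequence length).
#' @return A `skeleton_sequence` with T = `target`.
#' @export
resample_frames <- function(seq, target = 25L) {
  stopifnot(inherits(seq, "skeleton_sequence"), target >= 1L)
  t_n <- dim(seq$data)[2L]
  if (t_n < 1L) stop("sequence has no frames")
  if (t_n == target) return(seq)
  idx <- if (t_n > target) {
    floor((seq_len(target) - 1L) * t_n / target) + 1L
  } else {
    ((seq_len(target) - 1L) %% t_n) + 1L
  }
  out <- seq
  out$data <- seq$data[, idx, , , drop = FALSE]
  out
}

#' Random 3-D rotation augmentation
#'
#' Draws one angle triple uniformly from `[-max_degrees, +max_degrees]^3`
#' and applies the rotation `R = Rz %*% Ry %*% Rx` to the spatial channels of
#' every joint, frame and person, about the sequence's mean joint position
#' (computed over non-missing joints). Rotations are isometries: all
#' inter-joint distances are preserved. The confidence channel is untouched,
#' and exactly-zero (missing) joints stay zero.
#'
#' For 2-D data (spatial channels `"x","y"` only), only the in-plane
#' rotation is applied (`theta_x = theta_y = 0`).
#'
#' @param seq a [skeleton_sequence()].
#' @param max_degrees rotation bound in degrees (default 18, the standard
#'   augmentation range).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return The rotated `skeleton_sequence`.
#' @export
random_rotation_augment <- function(seq, max_degrees = 18, seed = NULL) {
  stopifnot(inherits(seq, "skeleton_sequence"), max_degrees >= 0)
  sp <- .spatial_channels(seq)
  if (length(sp) < 2L) {
    stop("rotation augmentation needs at least 2 spatial channels; ",
         "if a channel holds detector confidence, name it 'conf' so it is ",
         "treated as non-spatial")
  }
  if (!is.null(seed)) {
    restore <- .local_seed(seed)
    on.exit(restore(), add = TRUE)
  }
  theta <- stats::runif(3L, -max_degrees, max_degrees) * pi / 180
  if (length(sp) == 2L) theta[1:2] <- 0
  out <- seq
  out$data <- .rotate_spatial(seq$data, sp, theta)
  out
}

# Apply R = Rz Ry Rx to spatial channels `sp` of a (C,T,V,M) array about the
# mean non-missing joint position. Missing joints (all-zero across channels)
# are left untouched.
.rotate_spatial <- function(data, sp, theta) {
  d <- dim(data)
  rot <- .rotation_matrix(theta)
  # coordinates as 3 x (T*V*M), padding missing spatial dims with zeros
  coords <- matrix(0, 3L, prod(d[-1L]))
  for (i in seq_along(sp)) {
    coords[i, ] <- as.vector(data[sp[i], , , ])
  }
  present <- colSums(matrix(abs(data), d[1L]) ) > 0
  if (!any(present)) return(data)
  center <- rowMeans(coords[, present, drop = FALSE])
  rotated <- rot %*% (coords - center) + center
  for (i in seq_along(sp)) {
    slab <- data[sp[i], , , ]
    slab[] <- ifelse(present, rotated[i, ], 0)
    data[sp[i], , , ] <- slab
  }
  data
}

.rotation_matrix <- function(theta) {
  cx <- cos(theta[1L]); sx <- sin(theta[1L])
  cy <- cos(theta[2L]); sy <- sin(theta[2L])
  cz <- cos(theta[3L]); sz <- sin(theta[3L])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3L)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3L)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3L)
  rz %*% ry %*% rx
}

#' Center a sequence on its reference joint
#'
#' Translates the spatial channels so that the layout's center joint of
#' person 1, frame 1 sits at the origin. The same offset is applied to every
#' non-missing joint of every frame and person; zero-filled (missing) joints
#' and persons stay exactly zero. This makes downstream predictions
#' invariant to a constant coordinate offset of the whole recording.
#'
#' @param seq a [skeleton_sequence()].
#' @param layout the `skeleton_layout` naming the center joint.
#' @return The centered `skeleton_sequence`.
#' @export
normalize_coordinates <- function(seq, layout) {
  stopifnot(inherits(seq, "skeleton_sequence"),
            inherits(layout, "skeleton_layout"))
  sp <- .spatial_channels(seq)
  if (length(sp) == 0L) return(seq)
  d <- dim(seq$data)
  if (d[3L] != layout$num_joints) {
    stop("sequence has ", d[3L], " joints but layout '", layout$name,
         "' has ", layout$num_joints)
  }
  offset <- seq$data[sp, 1L, layout$center_joint, 1L]
  if (all(offset == 0)) return(seq)
  present <- colSums(matrix(abs(seq$data), d[1L])) > 0
  out <- seq
  for (i in seq_along(sp)) {
    slab <- out$data[sp[i], , , ]
    slab[] <- ifelse(present, as.vector(slab) - offset[i], 0)
    out$data[sp[i], , , ] <- slab
  }
  out
}

#' Bone-vector stream of a sequence
#'
#' The second input stream for two-stream fusion: each joint carries the
#' coordinate difference child - parent along the layout's bone edges
#' (parents point toward the layout's center joint); the center joint itself
#' carries zeros. The result has the same (C, T, V, M) shape as the joint
#' stream, so both streams share one architecture. Non-spatial channels are
#' copied through.
#'
#' @param seq a [skeleton_sequence()].
#' @param layout the `skeleton_layout` defining bones.
#' @return A `skeleton_sequence` of bone vectors.
#' @export
to_bone_stream <- function(seq, layout) {
  stopifnot(inherits(seq, "skeleton_sequence"),
            inherits(layout, "skeleton_layout"))
  sp <- .spatial_channels(seq)
  parent <- .parents_toward_center(layout)
  out <- seq
  d <- dim(seq$data)
  for (vj in seq_len(d[3L])) {
    p <- parent[vj]
    if (is.na(p)) {
      out$data[sp, , vj, ] <- 0
    } else {
      out$data[sp, , vj, ] <- seq$data[sp, , vj, ] - seq$data[sp, , p, ]
    }
  }
  out$meta$stream <- "bone"
  out
}

# parent of each joint on the tree rooted at the center joint (NA for root)
.parents_toward_center <- function(layout) {
  v <- layout$num_joints
  adj <- vector("list", v)
  for (i in seq_len(nrow(layout$edges))) {
    a <- layout$edges[i, 1L]; b <- layout$edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- rep(NA_integer_, v)
  seen <- logical(v)
  root <- layout$center_joint
  seen[root] <- TRUE
  frontier <- root
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (a in frontier) for (b in adj[[a]]) {
      if (!seen[b]) {
        seen[b] <- TRUE
        parent[b] <- a
        nxt <- c(nxt, b)
      }
    }
    frontier <- nxt
  }
  parent
}
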