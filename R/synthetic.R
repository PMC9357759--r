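#' Synthetic action generator specification
#'
#' Parameters of the forward-kinematic synthetic skeleton-action generator.
#' Each class is a tempo/amplitude profile for the skeleton's limb groups:
#' every limb (a subtree hanging off a branch point of the skeleton tree)
#' swings sinusoidally about its pivot joint, so bone lengths are preserved
#' exactly before noise. Classes differ by oscillation frequency (and, for
#' many classes, an amplitude tier), with a documented margin of at least
#' 0.015 cycles/frame between adjacent frequencies, which keeps the default
#' configuration linearly separable in the frequency domain.
#'
#' Sensor imperfections are emulated by i.i.d. Gaussian coordinate noise, a
#' per-joint confidence channel drawn around `conf_base`, and joint dropout:
#' with probability `conf_dropout` a joint's channels (coordinates and
#' confidence) are zeroed for one frame, the convention for missing
#' detections.
#'
#' @param num_classes number of action classes (default 4; 20 mirrors a
#'   sports-movement taxonomy).
#' @param frames frames per generated sequence before resampling
#'   (default 60).
#' @param layout_name skeleton layout (default `"synthetic20"`).
#' @param persons person slots M (default 2); person 2 is a phase-shifted
#'   copy of person 1 with independent noise, exercising the multi-person
#'   pathway.
#' @param noise_sigma standard deviation of additive Gaussian coordinate
#'   noise, in template units (default 0.01).
#' @param conf_base mean of the simulated detector confidence (default 0.9).
#' @param conf_dropout per-joint, per-frame probability of a zeroed
#'   (missing) detection (default 0.02).
#' @param limb_profiles optional per-class list of per-group motion
#'   parameters (`list(freq, amp, phase)` keyed by group root joint name);
#'   by default built by the margin-separated rule above.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(num_classes = 4L, frames = 60L,
                           layout_name = "synthetic20", persons = 2L,
                           noise_sigma = 0.01, conf_base = 0.9,
                           conf_dropout = 0.02, limb_profiles = NULL) {
  stopifnot(num_classes >= 1L, frames >= 2L, persons >= 1L,
            noise_sigma >= 0, conf_dropout >= 0, conf_dropout <= 1,
            conf_base >= 0, conf_base <= 1)
  layout <- build_layout(layout_name)
  groups <- .limb_groups(layout)
  if (is.null(limb_profiles)) {
    limb_profiles <- .default_profiles(groups, num_classes)
  }
  if (length(limb_profiles) != num_classes) {
    stop("limb_profiles must have one entry per class")
  }
  structure(
    list(num_classes = as.integer(num_classes), frames = as.integer(frames),
         layout_name = layout_name, persons = as.integer(persons),
         noise_sigma = noise_sigma, conf_base = conf_base,
         conf_dropout = conf_dropout, limb_profiles = limb_profiles,
         groups = groups),
    class = "synthetic_spec"
  )
}

# Limb groups of a skeleton tree: one group per joint whose parent (on the
# tree rooted at the center joint) is a branch point (degree >= 3) or the
# root itself; each joint belongs to the group of its nearest group-root
# ancestor. Returns a list of list(root, pivot, members, depth).
.limb_groups <- function(layout) {
  v <- layout$num_joints
  parent <- .parents_toward_center(layout)
  degree <- tabulate(c(layout$edges), nbins = v)
  root <- layout$center_joint
  is_group_root <- !is.na(parent) &
    (degree[parent] >= 3L | parent == root)
  depth <- integer(v)
  for (j in seq_len(v)) {
    p <- parent[j]; d <- 0L
    while (!is.na(p)) { d <- d + 1L; p <- parent[p] }
    depth[j] <- d
  }
  owner <- rep(NA_integer_, v)
  for (j in seq_len(v)) {
    a <- j
    while (!is.na(a)) {
      if (is_group_root[a]) { owner[j] <- a; break }
      a <- parent[a]
    }
  }
  roots <- which(is_group_root)
  roots <- roots[order(depth[roots])]
  ancestors <- function(j) {
    out <- integer(0)
    a <- parent[j]
    while (!is.na(a)) { out <- c(out, a); a <- parent[a] }
    out
  }
  lapply(roots, function(g) {
    sub <- which(vapply(seq_len(v),
                        function(j) j == g || g %in% ancestors(j), TRUE))
    list(name = layout$joint_names[g], root = g, pivot = parent[g],
         members = which(owner == g), subtree = sub, depth = depth[g])
  })
}

# Margin-separated class profiles: class k swings every limb at frequency
# f_k = 0.03 + 0.015 * ((k - 1) %% 12) cycles/frame, amplitude tier
# 1 + 0.3 * floor((k - 1) / 12); left/right limbs move in anti-phase.
.default_profiles <- function(groups, num_classes) {
  lapply(seq_len(num_classes), function(k) {
    freq <- 0.03 + 0.015 * ((k - 1L) %% 12L)
    tier <- 1 + 0.3 * ((k - 1L) %/% 12L)
    prof <- lapply(groups, function(g) {
      right <- grepl("^r_", g$name)
      amp <- if (grepl("hip|knee|leg", g$name)) 0.35
             else if (grepl("neck|head|spine", g$name)) 0.15
             else 0.5
      list(freq = freq, amp = amp * tier,
           phase = if (right) pi else 0)
    })
    names(prof) <- vapply(groups, `[[`, "", "name")
    prof
  })
}

#' Generate one synthetic action sequence
#'
#' Starts from the layout's template pose and drives each limb group with
#' its class's sinusoidal swing about the group's pivot joint (forward
#' kinematics, so all bone lengths are exactly preserved before noise),
#' then adds Gaussian coordinate noise, samples the confidence channel and
#' applies joint dropout. Deterministic for a fixed seed.
#'
#' @param class_id 1-based class index.
#' @param spec a [synthetic_spec()].
#' @param seed integer seed.
#' @return A [skeleton_sequence()] with channels (x, y, z, conf) and
#'   `label = class_id`.
#' @export
generate_action <- function(class_id, spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  class_id <- as.integer(class_id)
  if (class_id < 1L || class_id > spec$num_classes) {
    stop("unknown class_id ", class_id, " (spec has ", spec$num_classes,
         " classes)")
  }
  restore <- .local_seed(seed)
  on.exit(restore(), add = TRUE)
  layout <- build_layout(spec$layout_name)
  v <- layout$num_joints
  t_n <- spec$frames
  profile <- spec$limb_profiles[[class_id]]
  data <- array(0, c(4L, t_n, v, spec$persons))
  for (m in seq_len(spec$persons)) {
    # per-person kinematic jitter: small frequency/amplitude perturbations
    # and a person-level phase shift
    jit <- lapply(profile, function(p) {
      list(freq = p$freq * (1 + stats::runif(1L, -0.02, 0.02)),
           amp = p$amp * (1 + stats::runif(1L, -0.05, 0.05)),
           phase = p$phase + (m - 1L) * pi / 3 +
             stats::runif(1L, -0.3, 0.3))
    })
    for (t in seq_len(t_n)) {
      pose <- layout$template_pose
      for (g in spec$groups) {
        p <- jit[[g$name]]
        theta <- p$amp * sin(2 * pi * p$freq * (t - 1L) + p$phase)
        # rotate the entire subtree below the group root about its pivot's
        # current position: proper forward kinematics, so every bone length
        # is preserved exactly
        pivot <- pose[g$pivot, ]
        rot <- .rotation_matrix(c(0, 0, theta))
        sub <- g$subtree
        pose[sub, ] <- t(rot %*% (t(pose[sub, , drop = FALSE]) - pivot) +
                           pivot)
      }
      pose[, 1L] <- pose[, 1L] + (m - 1L) * 0.8   # offset second person
      data[1:3, t, , m] <- t(pose)
    }
  }
  if (spec$noise_sigma > 0) {
    data[1:3, , , ] <- data[1:3, , , ] +
      stats::rnorm(3L * t_n * v * spec$persons, 0, spec$noise_sigma)
  }
  conf <- pmin(pmax(stats::rnorm(t_n * v * spec$persons,
                                 spec$conf_base, 0.05), 0), 1)
  data[4L, , , ] <- conf
  if (spec$conf_dropout > 0) {
    drop <- stats::runif(t_n * v * spec$persons) < spec$conf_dropout
    if (any(drop)) {
      idx <- which(array(drop, c(t_n, v, spec$persons)), arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        data[, idx[r, 1L], idx[r, 2L], idx[r, 3L]] <- 0
      }
    }
  }
  skeleton_sequence(data, channels = c("x", "y", "z", "conf"),
                    label = class_id,
                    meta = list(source = "synthetic", seed = seed))
}

#' Generate a balanced labelled dataset
#'
#' `n_per_class` sequences per class, each generated with its own seed
#' derived from the master seed, so the dataset is fully reproducible and
#' per-sequence seeds are disjoint.
#'
#' @param spec a [synthetic_spec()].
#' @param n_per_class sequences per class.
#' @param seed master integer seed.
#' @return A [skeleton_dataset()].
#' @export
generate_dataset <- function(spec, n_per_class, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), n_per_class >= 1L)
  restore <- .local_seed(seed)
  n_total <- spec$num_classes * n_per_class
  seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  restore()
  labels <- rep(seq_len(spec$num_classes), each = n_per_class)
  sequences <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    sequences[[i]] <- generate_action(labels[i], spec, seed = seeds[i])
  }
  skeleton_dataset(sequences, labels, spec$layout_name)
}
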