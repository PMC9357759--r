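#' Skeleton layouts
#'
#' A skeleton layout is the static description of a body graph: joint names,
#' the bone edge list (the intra-frame edge set of the spatio-temporal
#' skeleton graph), a canonical template pose used to compute the
#' centroid-distance neighborhood partition, and the index of the joint used
#' as the reference for coordinate centering.
#'
#' Three layouts ship with the package:
#' \describe{
#'   \item{`"synthetic20"`}{the package default: a 20-joint tree with a
#'     standing T-pose template, matching the joint count of OpenPose-style
#'     20-keypoint input.}
#'   \item{`"coco18"`}{the 18-keypoint OpenPose COCO body model.}
#'   \item{`"ntu25"`}{the 25-joint Kinect-v2 body model used by the large
#'     motion-capture benchmarks.}
#' }
#'
#' Layout files are YAML with keys `version` (schema version, currently 1),
#' `name`, `joints` (V names), `edges` (list of 0-based index pairs),
#' `template_pose` (V x 3 coordinates) and `center_joint` (0-based index).
#' Indices are 0-based on disk and 1-based inside R.
#'
#' @param name one of `"synthetic20"`, `"coco18"`, `"ntu25"`, or a path to a
#'   layout YAML file.
#' @return A `skeleton_layout` object: a list with elements `name`,
#'   `num_joints`, `joint_names`, `edges` (E x 2 integer matrix, 1-based),
#'   `template_pose` (V x 3 matrix) and `center_joint` (1-based index).
#' @examples
#' lay <- build_layout("synthetic20")
#' lay$num_joints       # 20
#' nrow(lay$edges)      # 19, a spanning tree
#' @export
build_layout <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  builtin <- c("synthetic20", "coco18", "ntu25")
  path <- if (name %in% builtin) {
    system.file("extdata", "layouts", paste0(name, ".yaml"),
                package = "msstgcn", mustWork = TRUE)
  } else if (file.exists(name)) {
    name
  } else {
    stop("unknown layout '", name, "': expected one of ",
         paste(builtin, collapse = ", "), " or a path to a layout file")
  }
  spec <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop("malformed layout file '", path,
                                            "': ", conditionMessage(e)))
  required <- c("name", "joints", "edges", "template_pose", "center_joint")
  missing <- setdiff(required, names(spec))
  if (length(missing) > 0L) {
    stop("malformed layout file '", path, "': missing keys ",
         paste(missing, collapse = ", "))
  }
  v <- length(spec$joints)
  edges <- do.call(rbind, lapply(spec$edges, as.integer))
  template <- do.call(rbind, lapply(spec$template_pose, as.numeric))
  layout <- new_skeleton_layout(
    name = spec$name,
    joint_names = as.character(spec$joints),
    edges = edges + 1L,
    template_pose = template,
    center_joint = as.integer(spec$center_joint) + 1L
  )
  layout
}

#' Construct a skeleton layout from components
#'
#' Lower-level constructor used by [build_layout()] and by tests; validates
#' all layout invariants (index ranges, no self-loops or duplicate edges,
#' distinct template coordinates, connectivity).
#'
#' @param name layout identifier.
#' @param joint_names character vector of V joint names.
#' @param edges E x 2 integer matrix of 1-based joint index pairs.
#' @param template_pose V x 3 numeric matrix of canonical coordinates.
#' @param center_joint 1-based index of the centering reference joint.
#' @param require_tree if `TRUE` (default), require a connected tree
#'   (E = V - 1), the invariant all shipped layouts satisfy.
#' @return A validated `skeleton_layout`.
#' @export
new_skeleton_layout <- function(name, joint_names, edges, template_pose,
                                center_joint, require_tree = TRUE) {
  v <- length(joint_names)
  if (v < 1L) stop("layout must have at least one joint")
  edges <- matrix(as.integer(edges), ncol = 2L)
  template_pose <- matrix(as.numeric(template_pose), ncol = 3L)
  if (nrow(template_pose) != v) {
    stop("template_pose has ", nrow(template_pose), " rows; expected ", v)
  }
  if (nrow(edges) > 0L) {
    if (any(edges < 1L) || any(edges > v)) {
      stop("edge joint index out of range [1, ", v, "] in layout '", name, "'")
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loop edge in layout '", name, "'")
    }
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key)) stop("duplicate edge in layout '", name, "'")
  }
  # no two template joints may coincide (the partition needs distinct radii
  # geometry to be meaningful)
  d <- as.matrix(stats::dist(template_pose))
  diag(d) <- Inf
  if (any(d < 1e-12)) {
    stop("template_pose has coincident joints in layout '", name, "'")
  }
  if (isTRUE(require_tree)) {
    if (nrow(edges) != v - 1L || !.is_connected(v, edges)) {
      stop("layout '", name, "' must be a connected tree (|edges| = V - 1)")
    }
  }
  if (center_joint < 1L || center_joint > v) {
    stop("center_joint out of range in layout '", name, "'")
  }
  structure(
    list(name = name, num_joints = v, joint_names = joint_names,
         edges = edges, template_pose = template_pose,
         center_joint = as.integer(center_joint)),
    class = "skeleton_layout"
  )
}

.is_connected <- function(v, edges) {
  if (v == 1L) return(TRUE)
  if (nrow(edges) == 0L) return(FALSE)
  seen <- logical(v)
  seen[1L] <- TRUE
  frontier <- 1L
  adj <- vector("list", v)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  while (length(frontier) > 0L) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' @export
print.skeleton_layout <- function(x, ...) {
  cat("<skeleton_layout> ", x$name, ": ", x$num_joints, " joints, ",
      nrow(x$edges), " edges; center joint '",
      x$joint_names[x$center_joint], "'\n", sep = "")
  invisible(x)
}

#' Binary adjacency matrix of a skeleton layout
#'
#' One symmetric 1-pair per bone edge, zero diagonal (self-loops are added
#' later, during normalization).
#'
#' @param layout a `skeleton_layout`.
#' @return V x V symmetric 0/1 matrix with zero diagonal.
#' @examples
#' sum(adjacency_from_layout(build_layout("synthetic20"))) # 38 = 2 * 19
#' @export
adjacency_from_layout <- function(layout) {
  stopifnot(inherits(layout, "skeleton_layout"))
  v <- layout$num_joints
  a <- matrix(0, v, v, dimnames = list(layout$joint_names, layout$joint_names))
  if (nrow(layout$edges) > 0L) {
    a[layout$edges] <- 1
    a[layout$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  a
}
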