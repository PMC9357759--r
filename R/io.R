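#' Read OpenPose keypoint JSON output
#'
#' Reads a directory of per-frame OpenPose JSON files (one file per frame,
#' each with a `people` list whose entries carry a flat keypoint array of
#' (x, y, confidence) triples) into the raw per-frame detection structure
#' consumed by [select_top_persons()]. Frames are ordered by natural sort of
#' the file names (numeric runs compare numerically, so `frame_2` precedes
#' `frame_10`); the reader never reorders people within a frame. An empty
#' `people` list is legal and yields a frame with zero candidates.
#'
#' @param directory path containing `*.json` frame files.
#' @param layout the `skeleton_layout` the keypoints must match; a keypoint
#'   count differing from `layout$num_joints` is an error naming the file.
#' @param keypoints_field name of the per-person keypoint field (default
#'   `"pose_keypoints_2d"`; 3-D exports can name e.g. `"pose_keypoints_3d"`,
#'   read as (x, y, z, confidence) quadruples).
#' @return list of frames; each frame is a list of V x 3 (or V x 4) numeric
#'   matrices with channels (x, y, conf) (or (x, y, z, conf)).
#' @export
read_openpose_json <- function(directory, layout,
                               keypoints_field = "pose_keypoints_2d") {
  stopifnot(inherits(layout, "skeleton_layout"))
  if (!dir.exists(directory)) stop("no such directory: ", directory)
  files <- list.files(directory, pattern = "\\.json$", full.names = TRUE)
  if (length(files) == 0L) stop("no .json files in ", directory)
  files <- files[.natural_order(basename(files))]
  per_point <- if (grepl("_3d$", keypoints_field)) 4L else 3L
  v <- layout$num_joints
  lapply(files, function(f) {
    doc <- tryCatch(
      jsonlite::fromJSON(f, simplifyVector = FALSE),
      error = function(e) stop("malformed JSON in '", basename(f), "': ",
                               conditionMessage(e)))
    people <- doc$people
    if (is.null(people)) {
      stop("file '", basename(f), "' has no 'people' field")
    }
    lapply(people, function(p) {
      kp <- unlist(p[[keypoints_field]])
      if (is.null(kp)) {
        stop("file '", basename(f), "': person entry lacks '",
             keypoints_field, "'")
      }
      found <- length(kp) / per_point
      if (found != v) {
        stop("file '", basename(f), "': expected ", v,
             " keypoints for layout '", layout$name, "', found ", found)
      }
      matrix(as.numeric(kp), ncol = per_point, byrow = TRUE)
    })
  })
}

# natural sort order: digit runs compare numerically
.natural_order <- function(x) {
  keys <- gsub("(\\d+)", "~\\1~", x)
  parts <- strsplit(keys, "~")
  width <- 20L
  padded <- vapply(parts, function(p) {
    num <- grepl("^\\d+$", p)
    p[num] <- formatC(p[num], width = width, flag = "0")
    paste(p, collapse = "")
  }, "")
  order(padded, x)
}

#' Write / read the package's dataset archive
#'
#' A single-file, compressed, versioned archive holding a whole
#' [skeleton_dataset()]: the stacked (N, C, T, V, M) data array, the integer
#' labels, the layout name, the channel names and the schema version
#' (currently 1). Serialization is R-native and byte-stable, so
#' `read_dataset(write_dataset(x))` reproduces `x` bitwise. The archive
#' never reorders sequences, persons or frames.
#'
#' @param dataset a `skeleton_dataset`.
#' @param path file path (conventionally `*.rds`).
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns
#'   the `skeleton_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "skeleton_dataset"))
  obj <- list(
    format = "msstgcn-dataset",
    version = 1L,
    layout_name = dataset$layout_name,
    channels = dataset$channels,
    labels = dataset$labels,
    data = as_batch_array(dataset)
  )
  saveRDS(obj, path, compress = "gzip")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "msstgcn-dataset")) {
    stop("'", path, "' is not an msstgcn dataset archive")
  }
  if (!identical(obj$version, 1L)) {
    stop("dataset archive '", path, "' has schema version ", obj$version,
         "; this package reads version 1")
  }
  if (is.null(obj$labels)) {
    stop("dataset archive '", path, "' is missing the labels table")
  }
  if (is.null(obj$data) || length(dim(obj$data)) != 5L) {
    stop("dataset archive '", path, "' is missing the 5-D data array")
  }
  d <- dim(obj$data)
  sequences <- lapply(seq_len(d[1L]), function(i) {
    skeleton_sequence(array(obj$data[i, , , , ], d[-1L]),
                      channels = obj$channels,
                      label = obj$labels[i])
  })
  skeleton_dataset(sequences, obj$labels, obj$layout_name)
}

#' Default run configuration
#'
#' The nested configuration consumed by the command-line interface and
#' [read_run_config()]: model architecture, training settings (profile
#' `"table1"`: learning rate 0.001, batch size 10, 150 epochs) and fusion
#' weight (alpha = 0.6). Any field can be overridden from a YAML file or
#' from CLI flags.
#'
#' @return nested list with components `model`, `train` and `fusion`.
#' @export
default_run_config <- function() {
  list(
    model = list(num_classes = 4L, num_layers = 10L, gamma = 9L,
                 dropout = 0.25, layout_name = "synthetic20",
                 temporal_mode = "multiscale"),
    train = list(profile = "table1", learning_rate = 0.001,
                 batch_size = 10L, epochs = 150L, momentum = 0.9,
                 seed = 1L, augment = TRUE, max_degrees = 18),
    fusion = list(alpha = 0.6)
  )
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return nested configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}
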