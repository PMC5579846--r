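## Core domain types: sensor channel blocks, recordings, datasets, segments.
## All sample blocks are 3 x N real matrices: rows are the x, y, z axes of a
## tri-axial sensor, columns are time samples.

#' One tri-axial sensor's sample block
#'
#' Bundles a 3 x N matrix of samples with the identity of the sensor unit it
#' came from, the sensor type, and the sampling rate.
#'
#' @param unit_id Character scalar identifying the physical sensor unit.
#' @param sensor_type One of [SENSOR_TYPES].
#' @param samples Real 3 x N matrix (rows = x, y, z axes; columns = samples).
#' @param rate Sampling rate in Hz; must be positive.
#' @return An object of class `sensor_channel_set`.
#' @export
sensor_channel_set <- function(unit_id, sensor_type, samples, rate) {
  sensor_type <- match.arg(sensor_type, SENSOR_TYPES)
  samples <- as.matrix(samples)
  if (nrow(samples) != 3L)
    stop("samples must have exactly 3 rows (x, y, z axes), got ", nrow(samples))
  if (ncol(samples) < 1L) stop("samples must contain at least one column")
  if (!all(is.finite(samples))) stop("samples contain non-finite values")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a single positive number")
  structure(
    list(unit_id = as.character(unit_id), sensor_type = sensor_type,
         samples = unname(samples), rate = rate),
    class = "sensor_channel_set")
}

#' A labelled continuous recording
#'
#' One subject performing one activity, observed through a set of channel
#' blocks that all share the same length and sampling rate. A unit may
#' contribute at most one block per sensor type.
#'
#' @param subject_id,activity_id Character scalars.
#' @param channels List of [sensor_channel_set()] objects.
#' @return An object of class `recording`.
#' @export
recording <- function(subject_id, activity_id, channels) {
  if (length(channels) < 1L) stop("a recording needs at least one channel block")
  ok <- vapply(channels, inherits, logical(1), "sensor_channel_set")
  if (!all(ok)) stop("channels must all be sensor_channel_set objects")
  ns <- vapply(channels, function(ch) ncol(ch$samples), integer(1))
  rates <- vapply(channels, function(ch) ch$rate, numeric(1))
  if (length(unique(ns)) != 1L)
    stop("all channel blocks must share the same number of samples; got ",
         paste(unique(ns), collapse = ", "))
  if (length(unique(rates)) != 1L)
    stop("all channel blocks must share the same sampling rate")
  keys <- vapply(channels, function(ch) paste(ch$unit_id, ch$sensor_type, sep = "/"),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate (unit, sensor type) block: ", keys[duplicated(keys)][1L])
  structure(
    list(subject_id = as.character(subject_id),
         activity_id = as.character(activity_id),
         channels = channels, n_samples = ns[[1L]], rate = rates[[1L]],
         duration_s = ns[[1L]] / rates[[1L]]),
    class = "recording")
}

#' A labelled multi-subject dataset
#'
#' @param recordings List of [recording()] objects.
#' @param metadata List with elements `rate` (Hz), `units` (named list mapping
#'   unit id to a character vector of sensor types, in declared order),
#'   `activities` and `subjects` (character vectors), and optionally
#'   `window_s` / `overlap_fraction` segmentation defaults.
#' @return An object of class `oimotion_dataset`.
#' @export
oimotion_dataset <- function(recordings, metadata) {
  stopifnot(is.list(recordings), is.list(metadata))
  for (field in c("rate", "units", "activities", "subjects"))
    if (is.null(metadata[[field]])) stop("metadata is missing '", field, "'")
  allowed <- unlist(lapply(names(metadata$units), function(u)
    paste(u, metadata$units[[u]], sep = "/")))
  for (rec in recordings) {
    if (!inherits(rec, "recording")) stop("recordings must be recording objects")
    if (rec$rate != metadata$rate)
      stop("recording rate ", rec$rate, " does not match metadata rate ",
           metadata$rate)
    if (!rec$subject_id %in% metadata$subjects)
      stop("unknown subject '", rec$subject_id, "'")
    if (!rec$activity_id %in% metadata$activities)
      stop("unknown activity '", rec$activity_id, "'")
    keys <- vapply(rec$channels, function(ch)
      paste(ch$unit_id, ch$sensor_type, sep = "/"), character(1))
    bad <- setdiff(keys, allowed)
    if (length(bad))
      stop("recording contains undeclared channel block(s): ",
           paste(bad, collapse = ", "))
  }
  structure(list(recordings = recordings, metadata = metadata),
            class = "oimotion_dataset")
}

#' @export
print.oimotion_dataset <- function(x, ...) {
  md <- x$metadata
  cat("<oimotion_dataset>\n")
  cat("  subjects:  ", length(md$subjects),
      " activities: ", length(md$activities),
      " recordings: ", length(x$recordings), "\n", sep = "")
  cat("  units:     ", paste(names(md$units), collapse = ", "),
      " @ ", md$rate, " Hz\n", sep = "")
  invisible(x)
}

#' Pipeline configuration
#'
#' Carries the knobs shared across the processing chain: window length and
#' overlap, which of the five experimental cases to run, how many elements of
#' the heuristic transform to keep, and the PCA target dimensionality.
#'
#' @param window_s Window duration in seconds (default 5).
#' @param overlap_fraction Fraction of window overlap in `[0, 1)` (default 0).
#' @param case One of `"reference"`, `"random_rotation"`, `"euclidean_norm"`,
#'   `"heuristic"`, `"svd"`.
#' @param heuristic_elements 3, 6 or 9 leading channels of the heuristic
#'   transform (default 9).
#' @param pca_dims Number of retained principal components (default 30).
#' @param pca_fit_mode `"train_only"` fits the projection on training folds
#'   only; `"all_data"` pools training and test rows as in a whole-dataset
#'   pre-processing pass.
#' @param scale_fit_mode As `pca_fit_mode`, but for the per-sensor-type unit
#'   variance scales of the SVD transform.
#' @param seed Integer seed used for any randomized pipeline stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = 5, overlap_fraction = 0,
                            case = c("reference", "random_rotation",
                                     "euclidean_norm", "heuristic", "svd"),
                            heuristic_elements = 9L, pca_dims = 30L,
                            pca_fit_mode = c("train_only", "all_data"),
                            scale_fit_mode = c("train_only", "all_data"),
                            seed = 1L) {
  case <- match.arg(case)
  pca_fit_mode <- match.arg(pca_fit_mode)
  scale_fit_mode <- match.arg(scale_fit_mode)
  stopifnot(window_s > 0, overlap_fraction >= 0, overlap_fraction < 1,
            heuristic_elements %in% c(3L, 6L, 9L), pca_dims >= 1L)
  structure(list(window_s = window_s, overlap_fraction = overlap_fraction,
                 case = case, heuristic_elements = as.integer(heuristic_elements),
                 pca_dims = as.integer(pca_dims), pca_fit_mode = pca_fit_mode,
                 scale_fit_mode = scale_fit_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}
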