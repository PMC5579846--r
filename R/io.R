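## Dataset manifest + channel-file reader/writer.
##
## On-disk layout: a YAML manifest (`manifest.yml`) next to one delimited-text
## file per recording.  Each recording file has one row per time sample and a
## triplet of columns (x, y, z) per declared (unit, sensor type) block, in
## manifest order.  The separator and the presence of a header row are
## declared in the manifest.

manifest_channel_keys <- function(units) {
  unlist(lapply(names(units), function(u) paste(u, units[[u]], sep = "/")))
}

#' Read a dataset from a manifest
#'
#' @param manifest_path Path to a YAML manifest. Required keys: `rate` (Hz),
#'   `units` (map of unit id to list of sensor types), `subjects`,
#'   `activities`, `recordings` (list of maps with `subject`, `activity`,
#'   `file`), and optional `sep` (default `","`), `header` (default `FALSE`),
#'   `window_s`, `overlap_fraction`.
#' @return An [oimotion_dataset()].
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- yaml::read_yaml(manifest_path)
  for (field in c("rate", "units", "subjects", "activities", "recordings"))
    if (is.null(man[[field]])) stop("manifest is missing '", field, "': ",
                                    manifest_path)
  rate <- as.numeric(man$rate)
  if (!is.finite(rate) || rate <= 0)
    stop("manifest declares a non-positive sampling rate (", man$rate,
         "): ", manifest_path)
  units <- lapply(man$units, function(x) {
    x <- unlist(x)
    bad <- setdiff(x, SENSOR_TYPES)
    if (length(bad)) stop("unknown sensor type '", bad[1L], "' in manifest")
    x
  })
  sep <- if (is.null(man$sep)) "," else man$sep
  header <- isTRUE(man$header)
  base <- dirname(manifest_path)
  keys <- manifest_channel_keys(units)

  recs <- lapply(man$recordings, function(entry) {
    path <- file.path(base, entry$file)
    if (!file.exists(path))
      stop("channel file not found for recording (subject ", entry$subject,
           ", activity ", entry$activity, "): ", path)
    tab <- tryCatch(
      read.table(path, sep = sep, header = header, colClasses = "numeric"),
      error = function(e)
        stop("non-numeric or malformed cell in ", path, ": ",
             conditionMessage(e), call. = FALSE))
    need <- 3L * length(keys)
    if (ncol(tab) != need)
      stop("column-count mismatch in ", path, ": expected ", need,
           " (3 per declared sensor block), found ", ncol(tab))
    channels <- vector("list", length(keys))
    for (i in seq_along(keys)) {
      parts <- strsplit(keys[[i]], "/", fixed = TRUE)[[1L]]
      block <- t(as.matrix(tab[, (3L * i - 2L):(3L * i)]))
      if (!all(is.finite(block)))
        stop("non-finite value in ", path, " (block ", keys[[i]], ", first at row ",
             which(!apply(is.finite(block), 2, all))[1L], ")")
      channels[[i]] <- sensor_channel_set(parts[1L], parts[2L], block, rate)
    }
    recording(entry$subject, entry$activity, channels)
  })

  md <- list(rate = rate, units = units,
             subjects = as.character(unlist(man$subjects)),
             activities = as.character(unlist(man$activities)))
  if (!is.null(man$window_s)) md$window_s <- as.numeric(man$window_s)
  if (!is.null(man$overlap_fraction))
    md$overlap_fraction <- as.numeric(man$overlap_fraction)
  oimotion_dataset(recs, md)
}

#' Write a dataset as a manifest plus channel files
#'
#' Inverse of [read_dataset()]: emits `manifest.yml` and one CSV per
#' recording under `dir`. Numbers are written at full precision so a
#' write/read round trip reproduces the samples bit-identically.
#'
#' @param dataset An [oimotion_dataset()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "oimotion_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- dataset$metadata
  keys <- manifest_channel_keys(md$units)
  entries <- vector("list", length(dataset$recordings))
  for (i in seq_along(dataset$recordings)) {
    rec <- dataset$recordings[[i]]
    fname <- sprintf("rec_%03d.csv", i)
    have <- vapply(rec$channels, function(ch)
      paste(ch$unit_id, ch$sensor_type, sep = "/"), character(1))
    cols <- lapply(keys, function(k) {
      j <- match(k, have)
      if (is.na(j)) stop("recording ", i, " lacks declared block ", k)
      t(rec$channels[[j]]$samples)
    })
    tab <- do.call(cbind, cols)
    write.table(format(tab, digits = 17, trim = TRUE, scientific = TRUE),
                file.path(dir, fname), sep = ",", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    entries[[i]] <- list(subject = rec$subject_id, activity = rec$activity_id,
                         file = fname)
  }
  man <- list(rate = md$rate, sep = ",", header = FALSE,
              units = lapply(md$units, as.list),
              subjects = as.list(md$subjects),
              activities = as.list(md$activities),
              recordings = entries)
  if (!is.null(md$window_s)) man$window_s <- md$window_s
  if (!is.null(md$overlap_fraction)) man$overlap_fraction <- md$overlap_fraction
  path <- file.path(dir, "manifest.yml")
  yaml::write_yaml(man, path)
  invisible(path)
}
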