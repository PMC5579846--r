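## SVD-based orientation-invariant transformation.
##
## All sensor-type blocks of one unit within one segment are scaled to
## comparable (unit pooled variance) sensor units, concatenated column-wise
## into Vbar (3 x S*L), and decomposed as Vbar = U S W'.  The transform keeps
## S W' = U' Vbar: the segment re-expressed in its own principal axes, which
## discards the absolute orientation factor U.  Rotating the whole unit by a
## constant rotation R turns U into R U and leaves S W' unchanged up to the
## signs of the rows, which a deterministic sign canonicalization resolves.

#' Fit per-sensor-type variance scales
#'
#' For each sensor type present in the dataset, pools every sample value
#' (all axes, units, recordings) and computes the population standard
#' deviation. Dividing a type's data by its scale gives pooled unit variance,
#' equalizing the influence of sensor types with very different numeric
#' ranges on the joint SVD.
#'
#' @param dataset An [oimotion_dataset()], or a list of segments.
#' @return Named numeric vector of class `sensor_scales`
#'   (sensor type -> positive scale).
#' @export
fit_sensor_scales <- function(dataset) {
  blocks <- if (inherits(dataset, "oimotion_dataset")) {
    unlist(lapply(dataset$recordings, function(rec)
      lapply(rec$channels, function(ch)
        list(type = ch$sensor_type, samples = ch$samples))), recursive = FALSE)
  } else {
    unlist(lapply(dataset, function(seg)
      lapply(names(seg$blocks), function(key) {
        list(type = strsplit(key, "/", fixed = TRUE)[[1L]][2L],
             samples = seg$blocks[[key]])
      })), recursive = FALSE)
  }
  types <- unique(vapply(blocks, `[[`, character(1), "type"))
  scales <- vapply(types, function(tp) {
    vals <- unlist(lapply(blocks, function(b)
      if (b$type == tp) as.numeric(b$samples) else NULL))
    if (length(vals) < 2L)
      stop("sensor type '", tp, "' has fewer than 2 samples")
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))
    if (s == 0) stop("sensor type '", tp, "' has zero pooled variance")
    s
  }, numeric(1))
  structure(scales, class = "sensor_scales")
}

canonicalize_signs <- function(m) {
  ## flip each row so its largest-magnitude entry is positive; which.max
  ## resolves ties at the earliest column
  for (i in seq_len(nrow(m))) {
    j <- which.max(abs(m[i, ]))
    if (m[i, j] < 0) m[i, ] <- -m[i, ]
  }
  m
}

#' SVD-based orientation-invariant transform of one unit's segment
#'
#' @param unit_blocks Ordered (optionally named) list of 3 x L matrices, one
#'   per sensor type of the unit, all from the same segment.
#' @param scales [fit_sensor_scales()] output covering every sensor type in
#'   `sensor_types`.
#' @param sensor_types Character vector, parallel to `unit_blocks`, naming
#'   each block's sensor type. Defaults to `names(unit_blocks)`.
#' @return List of 3 x L matrices, parallel to the input: the rows of the
#'   sign-canonicalized `S W'`, split back into per-sensor blocks. Values
#'   stay in normalized (unit pooled variance) sensor units. Row `i` carries
#'   the component along the `i`-th principal axis; row variances over the
#'   concatenated segment are non-increasing. A rank-deficient segment (a
#'   singular value below `1e-12` times the largest) triggers a warning but
#'   still returns; noise makes this a measure-zero event in practice.
#' @export
svd_transform <- function(unit_blocks, scales, sensor_types = names(unit_blocks)) {
  stopifnot(length(unit_blocks) >= 1L)
  if (is.null(sensor_types))
    stop("sensor_types must be given when unit_blocks is unnamed")
  Ls <- vapply(unit_blocks, ncol, integer(1))
  if (length(unique(Ls)) != 1L)
    stop("all blocks of a unit must share the same segment length")
  missing <- setdiff(sensor_types, names(scales))
  if (length(missing))
    stop("no scale fitted for sensor type(s): ", paste(missing, collapse = ", "))
  scaled <- Map(function(b, tp) as.matrix(b) / scales[[tp]], unit_blocks, sensor_types)
  vbar <- do.call(cbind, scaled)
  sv <- svd(vbar, nu = 3L, nv = 3L)
  if (sv$d[3L] < 1e-12 * sv$d[1L])
    warning("degenerate (rank-deficient) segment: smallest singular value ",
            signif(sv$d[3L], 3), " vs largest ", signif(sv$d[1L], 3))
  out <- canonicalize_signs(diag(sv$d, 3L) %*% t(sv$v))
  L <- Ls[[1L]]
  res <- lapply(seq_along(unit_blocks), function(i)
    out[, ((i - 1L) * L + 1L):(i * L), drop = FALSE])
  names(res) <- names(unit_blocks)
  attr(res, "singular_values") <- sv$d
  res
}

#' Compact SVD factors of a 3 x N matrix
#'
#' Convenience accessor for tests and diagnostics: returns `U` (3 x 3),
#' the three non-increasing singular values, and `Wt` (3 x N with
#' orthonormal rows), so that `U %*% diag(S) %*% Wt` reconstructs the input.
#'
#' @param vbar Real 3 x N matrix.
#' @return List with elements `U`, `S`, `Wt`.
#' @export
svd_parts <- function(vbar) {
  sv <- svd(vbar, nu = 3L, nv = 3L)
  list(U = sv$u, S = sv$d, Wt = t(sv$v))
}

#' Apply the SVD transform to every unit of a segment
#'
#' Groups the segment's blocks by unit, jointly transforms each unit's
#' sensor-type blocks (one shared 3 x 3 rotational transformation per unit),
#' and returns the segment with blocks replaced.
#'
#' @param segment A segment.
#' @param scales [fit_sensor_scales()] output.
#' @return The transformed segment.
#' @export
svd_transform_segment <- function(segment, scales) {
  keys <- names(segment$blocks)
  parts <- strsplit(keys, "/", fixed = TRUE)
  units <- vapply(parts, `[[`, character(1), 1L)
  types <- vapply(parts, `[[`, character(1), 2L)
  for (u in unique(units)) {
    idx <- which(units == u)
    res <- svd_transform(segment$blocks[idx], scales, types[idx])
    for (k in seq_along(idx)) segment$blocks[[idx[k]]] <- res[[k]]
  }
  segment
}
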