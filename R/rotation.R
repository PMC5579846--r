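## Random-rotation simulation: proper rotation matrices from Euler angles,
## applied per segment and per unit (all sensor types of a unit share one
## orientation on the body, hence one matrix).

#' Rotation matrix from Euler angles
#'
#' Builds the triple product
#' `R = Rx(theta) %*% Ry(phi) %*% Rz(psi)`,
#' i.e. a rotation about x by `theta`, composed with a rotation about y by
#' `phi`, composed with a rotation about z by `psi`, in that order. The
#' result is always a proper rotation (orthonormal, determinant +1).
#'
#' @param theta,phi,psi Angles in radians.
#' @return A 3 x 3 rotation matrix.
#' @export
rotation_from_euler <- function(theta, phi, psi) {
  rx <- matrix(c(1, 0, 0,
                 0, cos(theta), -sin(theta),
                 0, sin(theta), cos(theta)), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(phi), 0, sin(phi),
                 0, 1, 0,
                 -sin(phi), 0, cos(phi)), 3, 3, byrow = TRUE)
  rz <- matrix(c(cos(psi), -sin(psi), 0,
                 sin(psi), cos(psi), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  rx %*% ry %*% rz
}

#' Draw a random rotation matrix
#'
#' The three Euler angles are drawn independently and uniformly from
#' `[0, 2*pi)` and fed to [rotation_from_euler()]. Note that uniform Euler
#' angles do not sample uniformly over the rotation group; this sampling
#' scheme is nonetheless the one used to emulate arbitrary sensor mounting.
#' Uses the current R random stream, so results are reproducible under
#' `set.seed()`.
#'
#' @return A 3 x 3 rotation matrix.
#' @export
random_rotation <- function() {
  a <- runif(3, 0, 2 * pi)
  rotation_from_euler(a[1L], a[2L], a[3L])
}

#' Check that a matrix is a proper rotation
#'
#' @param m A 3 x 3 matrix.
#' @param tol Elementwise tolerance for orthonormality and on `det(m) - 1`.
#' @return Logical scalar.
#' @export
is_rotation_matrix <- function(m, tol = 1e-10) {
  is.matrix(m) && all(dim(m) == c(3L, 3L)) &&
    max(abs(crossprod(m) - diag(3))) < tol &&
    abs(det(m) - 1) < tol
}

#' Rotate all blocks of a segment
#'
#' Left-multiplies every 3 x L block by its unit's rotation matrix. All
#' sensor types within a unit are rotated by the same matrix, mirroring a
#' physical re-orientation of that unit on the body. Labels are unchanged.
#'
#' @param segment A segment from [segment_recording()].
#' @param rotations Named list mapping unit id to a 3 x 3 rotation matrix;
#'   every unit present in the segment must have an entry.
#' @return The rotated segment.
#' @export
rotate_segment <- function(segment, rotations) {
  stopifnot(inherits(segment, "segment"))
  for (key in names(segment$blocks)) {
    unit <- strsplit(key, "/", fixed = TRUE)[[1L]][1L]
    R <- rotations[[unit]]
    if (is.null(R))
      stop("no rotation supplied for unit '", unit, "'")
    segment$blocks[[key]] <- R %*% segment$blocks[[key]]
  }
  segment
}

segment_units <- function(segment) {
  unique(vapply(strsplit(names(segment$blocks), "/", fixed = TRUE),
                `[[`, character(1), 1L))
}

#' Rotate every segment by fresh per-unit random rotations
#'
#' For each segment and each unit a new rotation matrix is drawn, emulating
#' sensor units mounted at arbitrary, independently chosen orientations in
#' every window.
#'
#' @param segments List of segments.
#' @param seed Integer seed for the rotation stream.
#' @return List with `segments` (rotated copies) and `log`, a list (one
#'   element per segment) of named lists of the 3 x 3 matrices applied.
#' @export
inject_rotations <- function(segments, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  logs <- vector("list", length(segments))
  out <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    units <- segment_units(segments[[i]])
    rots <- setNames(lapply(units, function(u) random_rotation()), units)
    out[[i]] <- rotate_segment(segments[[i]], rots)
    logs[[i]] <- rots
  }
  list(segments = out, log = logs)
}
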