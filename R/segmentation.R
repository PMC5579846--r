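## Window segmentation and the gravity high-pass utility.

#' Cut one recording into fixed-length windows
#'
#' Windows have length `L = round(window_s * rate)` samples and start at
#' multiples of `hop = round(L * (1 - overlap_fraction))`. Trailing samples
#' that do not fill a complete window are discarded; a recording shorter than
#' one window yields an empty list.
#'
#' @param rec A [recording()].
#' @param window_s Window duration in seconds.
#' @param overlap_fraction Fraction of overlap between consecutive windows,
#'   in `[0, 1)`. The common choices are 0 (non-overlapping) and 0.5.
#' @return List of `segment` objects. Each carries the recording's labels and
#'   a named list `blocks` mapping `"unit/sensor_type"` to a 3 x L matrix.
#' @export
segment_recording <- function(rec, window_s, overlap_fraction = 0) {
  stopifnot(inherits(rec, "recording"),
            overlap_fraction >= 0, overlap_fraction < 1)
  L <- as.integer(round(window_s * rec$rate))
  if (L < 1L) stop("window of ", window_s, " s at ", rec$rate,
                   " Hz is shorter than one sample")
  hop <- max(1L, as.integer(round(L * (1 - overlap_fraction))))
  N <- rec$n_samples
  if (N < L) return(list())
  starts <- seq.int(1L, N - L + 1L, by = hop)
  keys <- vapply(rec$channels, function(ch)
    paste(ch$unit_id, ch$sensor_type, sep = "/"), character(1))
  lapply(seq_along(starts), function(i) {
    s <- starts[[i]]
    blocks <- lapply(rec$channels, function(ch) ch$samples[, s:(s + L - 1L), drop = FALSE])
    names(blocks) <- keys
    structure(list(subject_id = rec$subject_id, activity_id = rec$activity_id,
                   blocks = blocks, L = L, rate = rec$rate,
                   segment_index = i),
              class = "segment")
  })
}

#' Segment every recording of a dataset
#'
#' @param dataset An [oimotion_dataset()].
#' @inheritParams segment_recording
#' @return Flat list of segments, in recording order.
#' @export
segment_dataset <- function(dataset, window_s = NULL, overlap_fraction = NULL) {
  stopifnot(inherits(dataset, "oimotion_dataset"))
  md <- dataset$metadata
  if (is.null(window_s)) window_s <- if (!is.null(md$window_s)) md$window_s else 5
  if (is.null(overlap_fraction))
    overlap_fraction <- if (!is.null(md$overlap_fraction)) md$overlap_fraction else 0
  out <- lapply(dataset$recordings, segment_recording,
                window_s = window_s, overlap_fraction = overlap_fraction)
  do.call(c, out)
}

#' Remove the gravity component from an acceleration block
#'
#' Zero-phase (forward-backward) second-order Butterworth high-pass applied
#' per axis, after removing each axis mean. Intended to derive a
#' body-acceleration channel comparable to smartphone datasets that ship one;
#' the exact filter those providers used is not claimed to be matched.
#'
#' @param block Real 3 x N matrix.
#' @param rate Sampling rate in Hz.
#' @param cutoff High-pass cutoff in Hz; must lie in `(0, rate/2)`.
#'   Default 0.3 Hz, a conventional body/gravity separation point.
#' @return A 3 x N matrix with the quasi-static component attenuated.
#' @export
gravity_highpass <- function(block, rate, cutoff = 0.3) {
  block <- as.matrix(block)
  stopifnot(nrow(block) == 3L)
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= rate / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist rate ",
         rate / 2, " Hz, got ", cutoff)
  bf <- signal::butter(2, cutoff / (rate / 2), type = "high")
  out <- block
  for (ax in 1:3) {
    x <- block[ax, ]
    x <- x - mean(x)
    # mean removal first: avoids filtfilt edge transients on a pure offset
    out[ax, ] <- if (all(x == 0)) x else signal::filtfilt(bf, x)
  }
  out
}
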