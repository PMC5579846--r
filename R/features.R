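## Per-axis statistical/spectral features, per-subject [0,1] normalization,
## and PCA reduction.
##
## Per channel the feature vector is, in fixed order: min, max, mean,
## skewness, kurtosis; the autocorrelation at lag 0 (the variance) and at
## every fifth lag up to 50 that fits in the segment; and the five largest
## DFT peak magnitudes with their frequencies.  For a 125-sample segment this
## gives 26 features per channel; for a 40-sample one, 23 (lags above 35 do
## not fit, while the DFT peak slots are zero-padded to fixed width).

#' Feature extraction specification
#'
#' @param autocorr_max_lag Largest candidate autocorrelation lag (default 50).
#' @param autocorr_step Lag spacing (default 5). The lag set is 0 plus every
#'   multiple of the step up to the maximum, restricted to lags `<= L - 1`.
#' @param n_dft_peaks Number of DFT peak (magnitude, frequency) pairs
#'   (default 5); missing peaks are zero-filled so the width is fixed.
#' @param dft_min_separation Minimum bin distance between any two selected
#'   peaks (default 11).
#' @param include_minmax Include per-channel min and max (default `TRUE`).
#'   This is the configuration whose per-channel counts match the reference
#'   totals; disabling it drops two features per channel.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(autocorr_max_lag = 50L, autocorr_step = 5L,
                         n_dft_peaks = 5L, dft_min_separation = 11L,
                         include_minmax = TRUE) {
  stopifnot(n_dft_peaks >= 1L, dft_min_separation >= 1L,
            autocorr_step >= 1L, autocorr_max_lag >= autocorr_step)
  structure(list(autocorr_max_lag = as.integer(autocorr_max_lag),
                 autocorr_step = as.integer(autocorr_step),
                 n_dft_peaks = as.integer(n_dft_peaks),
                 dft_min_separation = as.integer(dft_min_separation),
                 include_minmax = isTRUE(include_minmax)),
            class = "feature_spec")
}

feature_lag_set <- function(spec, L) {
  lags <- seq.int(spec$autocorr_step, spec$autocorr_max_lag,
                  by = spec$autocorr_step)
  c(0L, lags[lags <= L - 1L])
}

#' Biased, mean-removed autocorrelation at chosen lags
#'
#' `a(l) = (1/L) * sum_{n=0}^{L-1-l} (x[n] - xbar)(x[n+l] - xbar)`, so that
#' `a(0)` is exactly the population variance of `x`.
#'
#' @param x Numeric sequence of length L.
#' @param lags Integer lags, each in `[0, L - 1]`.
#' @return Numeric vector of the same length as `lags`.
#' @export
autocorrelation <- function(x, lags) {
  L <- length(x)
  if (any(lags < 0L | lags >= L))
    stop("lags must lie in [0, ", L - 1L, "]")
  xc <- x - mean(x)
  vapply(as.integer(lags), function(l) {
    if (l == 0L) return(mean(xc * xc))
    sum(xc[1:(L - l)] * xc[(1L + l):L]) / L
  }, numeric(1))
}

#' Largest DFT peaks with a minimum bin separation
#'
#' Computes the magnitude spectrum over the one-sided bins `0 .. floor(L/2)`
#' and selects peaks greedily, largest first, rejecting any bin closer than
#' `min_separation` bins to an already selected peak. Frequencies are
#' reported in Hz as `bin * rate / L`. If fewer than `n_peaks` admissible
#' peaks exist, the remaining slots are zero-filled so the output width is
#' fixed.
#'
#' @param x Numeric sequence of length `L >= 2`.
#' @param rate Sampling rate in Hz.
#' @param n_peaks Number of peaks to report.
#' @param min_separation Minimum pairwise bin distance between peaks.
#' @return List with `magnitudes` and `frequencies`, each of length `n_peaks`.
#' @export
dft_peaks <- function(x, rate, n_peaks = 5L, min_separation = 11L) {
  L <- length(x)
  stopifnot(L >= 2L)
  mag <- Mod(fft(x))[1:(floor(L / 2) + 1L)]
  bins <- seq_along(mag) - 1L
  mags <- numeric(n_peaks)
  freqs <- numeric(n_peaks)
  taken <- integer(0)
  ord <- order(mag, decreasing = TRUE)
  k <- 0L
  for (j in ord) {
    if (k >= n_peaks) break
    b <- bins[[j]]
    if (length(taken) && min(abs(taken - b)) < min_separation) next
    k <- k + 1L
    mags[[k]] <- mag[[j]]
    freqs[[k]] <- b * rate / L
    taken <- c(taken, b)
  }
  list(magnitudes = mags, frequencies = freqs)
}

moment_stats <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) {
    c(mean = m, skewness = 0, kurtosis = 0)
  } else {
    ## population moments; kurtosis is non-excess (Gaussian -> 3)
    c(mean = m,
      skewness = mean((x - m)^3) / v^1.5,
      kurtosis = mean((x - m)^4) / v^2)
  }
}

#' Feature vector of one segment
#'
#' Concatenates, channel by channel in the given (deterministic) order:
#' min, max, mean, skewness, kurtosis, the autocorrelation lag set (variance
#' first), and `n_dft_peaks` DFT magnitudes followed by their frequencies.
#'
#' @param channels Named list of equal-length numeric sequences (one per
#'   axis of the possibly transformed segment).
#' @param spec A [feature_spec()].
#' @param rate Sampling rate in Hz (for peak frequencies).
#' @return Named numeric vector; names are `<channel>.<feature>`.
#' @export
extract_features <- function(channels, spec = feature_spec(), rate) {
  stopifnot(length(channels) >= 1L)
  Ls <- lengths(channels)
  if (length(unique(Ls)) != 1L) stop("channels differ in length")
  L <- Ls[[1L]]
  if (L < 2L) stop("channels must contain at least 2 samples")
  lags <- feature_lag_set(spec, L)
  out <- lapply(names(channels), function(nm) {
    x <- as.numeric(channels[[nm]])
    if (!all(is.finite(x))) stop("non-finite value in channel '", nm, "'")
    ms <- moment_stats(x)
    ac <- autocorrelation(x, lags)
    pk <- dft_peaks(x, rate, spec$n_dft_peaks, spec$dft_min_separation)
    vals <- c(if (spec$include_minmax) c(min = min(x), max = max(x)),
              ms, setNames(ac, paste0("ac", lags)),
              setNames(pk$magnitudes, paste0("dftmag", seq_along(pk$magnitudes))),
              setNames(pk$frequencies, paste0("dftfreq", seq_along(pk$frequencies))))
    setNames(vals, paste(nm, names(vals), sep = "."))
  })
  unlist(out)
}

#' Number of features per channel for a given segment length
#'
#' Closed-form count: base statistics + surviving autocorrelation lags +
#' `2 * n_dft_peaks`.
#'
#' @inheritParams extract_features
#' @param L Segment length in samples.
#' @return Integer.
#' @export
features_per_channel <- function(L, spec = feature_spec()) {
  base <- 3L + if (spec$include_minmax) 2L else 0L
  base + length(feature_lag_set(spec, L)) + 2L * spec$n_dft_peaks
}

#' Build a feature table from segments
#'
#' One row per segment: `subject_id`, `activity_id`, `segment_index` label
#' columns followed by the feature columns. Channels are ordered by unit and
#' sensor type as they appear in the segment's block list, then by row
#' (axis or transformed channel) order.
#'
#' @param segments List of segments whose blocks are the (possibly
#'   transformed) channel matrices.
#' @param spec A [feature_spec()].
#' @return A `data.frame` feature table.
#' @export
build_feature_table <- function(segments, spec = feature_spec()) {
  stopifnot(length(segments) >= 1L)
  rows <- lapply(segments, function(seg) {
    chans <- list()
    for (key in names(seg$blocks)) {
      b <- seg$blocks[[key]]
      rn <- rownames(b)
      if (is.null(rn)) rn <- paste0("ax", seq_len(nrow(b)))
      for (i in seq_len(nrow(b)))
        chans[[paste(key, rn[[i]], sep = ".")]] <- b[i, ]
    }
    extract_features(chans, spec, seg$rate)
  })
  feats <- do.call(rbind, rows)
  labels <- data.frame(
    subject_id = vapply(segments, `[[`, character(1), "subject_id"),
    activity_id = vapply(segments, `[[`, character(1), "activity_id"),
    segment_index = vapply(segments, function(s) as.integer(s$segment_index),
                           integer(1)),
    stringsAsFactors = FALSE)
  cbind(labels, as.data.frame(feats, check.names = FALSE))
}

label_columns <- c("subject_id", "activity_id", "segment_index")

#' Numeric feature matrix of a feature table
#' @param table A feature table from [build_feature_table()].
#' @return Numeric matrix without the label columns.
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, setdiff(colnames(table), label_columns), drop = FALSE])
}

#' Min-max normalize features within each subject
#'
#' Every feature column is rescaled to `[0, 1]` independently for each
#' subject, using that subject's own minimum and maximum. A column constant
#' within a subject maps to 0. Idempotent on already-normalized tables.
#'
#' @param table A feature table.
#' @return The normalized table.
#' @export
normalize_per_subject <- function(table) {
  stopifnot(nrow(table) >= 1L)
  fcols <- setdiff(colnames(table), label_columns)
  for (subj in unique(table$subject_id)) {
    idx <- table$subject_id == subj
    block <- as.matrix(table[idx, fcols, drop = FALSE])
    lo <- apply(block, 2L, min)
    hi <- apply(block, 2L, max)
    rng <- hi - lo
    rng[rng == 0] <- 1          # constant columns map to 0
    table[idx, fcols] <- sweep(sweep(block, 2L, lo, "-"), 2L, rng, "/")
  }
  table
}

pca_fit <- function(x) {
  mu <- colMeans(x)
  eg <- eigen(cov(x), symmetric = TRUE)
  list(mean = mu, vectors = eg$vectors, values = pmax(eg$values, 0))
}

#' Reduce train and test feature tables to M principal components
#'
#' Principal directions come from the covariance of the fitting set: the
#' training rows (`fit_mode = "train_only"`, the leakage-free default) or the
#' pooled train and test rows (`fit_mode = "all_data"`, a whole-dataset
#' pre-processing pass). Both tables are centered with the fitting mean and
#' projected on the first `M` eigenvectors, sorted by non-increasing
#' eigenvalue.
#'
#' @param train,test Feature tables with identical feature columns.
#' @param M Number of retained components; must not exceed the feature count.
#' @param fit_mode `"train_only"` or `"all_data"`.
#' @return List with `train`, `test` (tables whose feature columns are
#'   `PC1..PCM`) and `eigenvalues` (all, non-increasing).
#' @export
pca_reduce <- function(train, test, M, fit_mode = c("train_only", "all_data")) {
  fit_mode <- match.arg(fit_mode)
  xtr <- feature_matrix(train)
  xte <- feature_matrix(test)
  if (M > ncol(xtr))
    stop("M = ", M, " exceeds the number of features (", ncol(xtr), ")")
  fit <- pca_fit(if (fit_mode == "all_data") rbind(xtr, xte) else xtr)
  proj <- function(x) sweep(x, 2L, fit$mean, "-") %*% fit$vectors[, seq_len(M), drop = FALSE]
  wrap <- function(tab, x) {
    p <- as.data.frame(x)
    colnames(p) <- paste0("PC", seq_len(M))
    cbind(tab[, intersect(label_columns, colnames(tab)), drop = FALSE], p)
  }
  list(train = wrap(train, proj(xtr)), test = wrap(test, proj(xte)),
       eigenvalues = fit$values)
}

#' Leading eigenvalues of the feature covariance
#'
#' Supports scree plots for choosing the PCA dimensionality.
#'
#' @param table A feature table.
#' @param n Number of leading eigenvalues to return.
#' @return Numeric vector of length `n`, non-increasing.
#' @export
scree <- function(table, n) {
  ev <- pca_fit(feature_matrix(table))$values
  head(ev, n)
}
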