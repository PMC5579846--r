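test_that("autocorrelation is biased and mean-removed, with a(0) the variance", {
  x <- c(1, -1, 1, -1)
  expect_equal(autocorrelation(x, 0), 1)
  expect_equal(autocorrelation(rep(3, 10), 0:5), rep(0, 6))
  expect_error(autocorrelation(x, 4), "lags")
  # white noise: normalized autocorrelation at the feature lags is small
  set.seed(41)
  x <- rnorm(1e4)
  a <- autocorrelation(x, c(0, seq(5, 50, 5)))
  expect_true(all(abs(a[-1]) / a[1] < 0.05))
  # a(0) equals the population variance bit-for-bit
  set.seed(42)
  y <- rnorm(125)
  expect_identical(autocorrelation(y, 0), mean((y - mean(y))^2))
})

test_that("DFT peaks are greedy with a minimum bin separation, zero-filled", {
  n <- 0:127
  x <- cos(2 * pi * 10 * n / 128)
  pk <- dft_peaks(x, rate = 50)
  expect_equal(pk$frequencies[1], 10 * 50 / 128)
  expect_equal(pk$magnitudes[1], 64, tolerance = 1e-8)

  pk2 <- dft_peaks(rep(2, 64), rate = 50)
  expect_equal(pk2$frequencies[1], 0)
  expect_equal(pk2$magnitudes[1], 128)
  expect_equal(pk2$magnitudes[2:5], rep(0, 4))

  # 21 one-sided bins with exclusion radius 10 admit at most 2 peaks
  set.seed(43)
  pk3 <- dft_peaks(rnorm(40), rate = 8)
  expect_length(pk3$magnitudes, 5)
  expect_length(pk3$frequencies, 5)
  expect_identical(sum(pk3$magnitudes > 0), 2L)
  # selected bins respect the separation
  bins <- round(pk3$frequencies[pk3$magnitudes > 0] * 40 / 8)
  expect_gte(abs(diff(bins)), 11)
})

test_that("per-channel feature counts follow the segment length", {
  expect_identical(features_per_channel(125), 26L)
  expect_identical(features_per_channel(40), 23L)
  expect_identical(features_per_channel(128), 26L)
  set.seed(44)
  for (L in c(40, 125, 128, 260)) {
    v <- extract_features(list(ch = rnorm(L)), rate = 25)
    expect_length(v, features_per_channel(L))
  }
})

test_that("degenerate constant channels follow the pinned conventions", {
  v <- extract_features(list(flat = rep(4, 50), live = rnorm(50)), rate = 25)
  expect_equal(unname(v["flat.min"]), 4)
  expect_equal(unname(v["flat.max"]), 4)
  expect_equal(unname(v["flat.mean"]), 4)
  expect_equal(unname(v["flat.skewness"]), 0)
  expect_equal(unname(v["flat.kurtosis"]), 0)
  expect_equal(unname(v["flat.ac0"]), 0)
  expect_error(extract_features(list(bad = c(1, NA, 3)), rate = 25),
               "non-finite")
  expect_error(extract_features(list(a = 1:5, b = 1:6), rate = 25),
               "differ in length")
})

test_that("moment features match direct population formulas", {
  set.seed(45)
  x <- rexp(200)
  v <- extract_features(list(x = x), rate = 25)
  m <- mean(x); s2 <- mean((x - m)^2)
  expect_equal(unname(v["x.skewness"]), mean((x - m)^3) / s2^1.5)
  expect_equal(unname(v["x.kurtosis"]), mean((x - m)^4) / s2^2)
  expect_identical(unname(v["x.ac0"]), s2)
})

test_that("per-subject normalization maps each subject to [0, 1] independently", {
  tab <- data.frame(subject_id = c("a", "a", "a", "b", "b"),
                    activity_id = "A1", segment_index = 1:5,
                    f1 = c(2, 4, 6, 100, 200), f2 = c(1, 1, 1, 0, 5))
  out <- normalize_per_subject(tab)
  expect_equal(out$f1, c(0, 0.5, 1, 0, 1))
  expect_equal(out$f2[1:3], c(0, 0, 0))     # constant within subject -> 0
  expect_equal(out$f2[4:5], c(0, 1))
  # idempotent
  expect_equal(normalize_per_subject(out), out)
})

test_that("PCA projects on descending-eigenvalue directions", {
  set.seed(46)
  n <- 200
  base <- matrix(rnorm(n * 2), n, 2)
  x <- cbind(base %*% c(1, 1), base %*% c(1, -1) * 0.01)  # dominant (1,1)
  tab <- data.frame(subject_id = "s", activity_id = rep(c("A", "B"), n / 2),
                    segment_index = seq_len(n), x, check.names = FALSE)
  colnames(tab)[4:5] <- c("f1", "f2")
  red <- pca_reduce(tab[1:150, ], tab[151:200, ], M = 1)
  expect_true(all(diff(red$eigenvalues) <= 1e-12))
  # projected variance captures nearly all total variance
  expect_gte(var(red$train$PC1), 0.99 * sum(red$eigenvalues))
  expect_error(pca_reduce(tab[1:150, ], tab[151:200, ], M = 5), "exceeds")

  # eigenvalue sum equals total feature variance (trace identity)
  ev <- scree(tab, 2)
  expect_equal(sum(ev), sum(apply(tab[, 4:5], 2, var)), tolerance = 1e-8)
})

test_that("feature tables are rectangular, labelled and NaN-free", {
  segs <- segment_recording(toy_recording(N = 250), 2, 0)
  tab <- build_feature_table(segs)
  expect_identical(nrow(tab), length(segs))
  expect_true(all(c("subject_id", "activity_id", "segment_index") %in%
                    colnames(tab)))
  expect_false(anyDuplicated(colnames(tab)) > 0)
  expect_true(all(is.finite(feature_matrix(tab))))
  # 2 sensors x 3 axes, L = 50 -> 6 channels x 21 features each
  expect_identical(ncol(feature_matrix(tab)), 6L * features_per_channel(50L))
  norm <- normalize_per_subject(tab)
  fm <- feature_matrix(norm)
  expect_true(all(fm >= 0 & fm <= 1))
})
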