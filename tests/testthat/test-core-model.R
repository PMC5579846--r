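test_that("dataset write/read round trip reproduces samples bit-identically", {
  ds <- generate_dataset(tiny_config(seed = 3))
  dir <- withr::local_tempdir()
  path <- write_dataset(ds, dir)
  back <- read_dataset(path)
  expect_equal(length(back$recordings), length(ds$recordings))
  for (i in seq_along(ds$recordings)) {
    for (j in seq_along(ds$recordings[[i]]$channels)) {
      expect_identical(back$recordings[[i]]$channels[[j]]$samples,
                       ds$recordings[[i]]$channels[[j]]$samples)
    }
    expect_identical(back$recordings[[i]]$subject_id,
                     ds$recordings[[i]]$subject_id)
  }
  expect_identical(back$metadata$units, lapply(ds$metadata$units, as.character))
})

test_that("reader errors carry file context", {
  dir <- withr::local_tempdir()
  write_dataset(toy_dataset(), dir)
  man <- yaml::read_yaml(file.path(dir, "manifest.yml"))

  # missing channel file names the recording
  man2 <- man
  man2$recordings[[1]]$file <- "nope.csv"
  yaml::write_yaml(man2, file.path(dir, "m2.yml"))
  expect_error(read_dataset(file.path(dir, "m2.yml")), "S01.*A01|nope.csv")

  # declared sensor block with no matching columns
  man3 <- man
  man3$units$U1 <- c(man3$units$U1, "magnetometer")
  yaml::write_yaml(man3, file.path(dir, "m3.yml"))
  expect_error(read_dataset(file.path(dir, "m3.yml")), "column-count mismatch")

  # non-numeric cell
  lines <- readLines(file.path(dir, "rec_001.csv"))
  lines[5] <- sub("^[^,]*", "oops", lines[5])
  writeLines(lines, file.path(dir, "rec_bad.csv"))
  man4 <- man
  man4$recordings[[1]]$file <- "rec_bad.csv"
  yaml::write_yaml(man4, file.path(dir, "m4.yml"))
  expect_error(read_dataset(file.path(dir, "m4.yml")), "rec_bad.csv")

  # non-positive rate
  man5 <- man
  man5$rate <- 0
  yaml::write_yaml(man5, file.path(dir, "m5.yml"))
  expect_error(read_dataset(file.path(dir, "m5.yml")), "rate")
})

test_that("type constructors enforce their invariants", {
  expect_error(sensor_channel_set("U1", "accelerometer", matrix(0, 2, 5), 25),
               "3 rows")
  expect_error(sensor_channel_set("U1", "accelerometer",
                                  matrix(c(1, NA, rep(0, 4)), 3, 2), 25),
               "non-finite")
  expect_error(sensor_channel_set("U1", "accelerometer", matrix(0, 3, 5), 0),
               "positive")
  ch <- sensor_channel_set("U1", "accelerometer", matrix(0, 3, 5), 25)
  expect_error(recording("S", "A", list(ch, ch)), "duplicate")
  ch2 <- sensor_channel_set("U1", "gyroscope", matrix(0, 3, 6), 25)
  expect_error(recording("S", "A", list(ch, ch2)), "same number of samples")
})

test_that("segmentation reproduces the window lengths of common configurations", {
  # 7500 samples at 25 Hz, 5 s windows, no overlap -> 60 segments of 125
  rec <- recording("S01", "A01", list(
    sensor_channel_set("U1", "accelerometer", matrix(rnorm(3 * 7500), 3), 25)))
  segs <- segment_recording(rec, 5, 0)
  expect_length(segs, 60)
  expect_true(all(vapply(segs, `[[`, integer(1), "L") == 125L))

  # 50 Hz, 2.56 s windows, 50% overlap -> L = 128, hop = 64
  rec2 <- recording("S01", "A01", list(
    sensor_channel_set("U1", "accelerometer", matrix(rnorm(3 * 1000), 3), 50)))
  segs2 <- segment_recording(rec2, 2.56, 0.5)
  expect_identical(segs2[[1]]$L, 128L)
  expect_identical(segs2[[2]]$blocks[[1]][, 1],
                   rec2$channels[[1]]$samples[, 65])

  # shorter than one window -> empty, not an error
  rec3 <- recording("S01", "A01", list(
    sensor_channel_set("U1", "accelerometer", matrix(rnorm(300), 3), 50)))
  expect_identical(segment_recording(rec3, 2.56, 0), list())
})

test_that("segment count matches brute-force window enumeration", {
  set.seed(11)
  for (trial in 1:20) {
    N <- sample(50:900, 1)
    rate <- sample(c(8, 25, 50), 1)
    window_s <- sample(c(1, 2.56, 5), 1)
    overlap <- sample(c(0, 0.25, 0.5), 1)
    L <- round(window_s * rate)
    hop <- max(1, round(L * (1 - overlap)))
    rec <- recording("S", "A", list(
      sensor_channel_set("U1", "accelerometer", matrix(rnorm(3 * N), 3), rate)))
    got <- length(segment_recording(rec, window_s, overlap))
    brute <- sum(seq(1, N, by = hop) + L - 1 <= N)
    expect_identical(got, as.integer(brute))
    expect_identical(got, as.integer(max(0, floor((N - L) / hop) + 1)))
  }
})

test_that("gravity high-pass rejects DC and passes high frequencies", {
  const <- matrix(5.5, 3, 200)
  expect_lt(max(abs(gravity_highpass(const, 25))), 1e-12)

  t <- 0:499
  s <- rbind(sin(2 * pi * 5 * t / 25), 0 * t, 0 * t) + c(9.8, 0, 0)
  out <- gravity_highpass(s, 25, cutoff = 0.3)
  mid <- 100:400
  expect_lt(max(abs(out[1, mid] - sin(2 * pi * 5 * t[mid] / 25))), 0.05)
  expect_lt(max(abs(out[2, ])), 1e-12)

  expect_error(gravity_highpass(const, 25, cutoff = 12.5), "Nyquist")
  expect_error(gravity_highpass(const, 25, cutoff = 0), "Nyquist")
})
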