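# Small fixtures shared across test files; everything is generated in code.

tiny_config <- function(seed = 1L, ...) {
  synth_config(n_subjects = 3L, n_activities = 3L, n_units = 1L,
               rate = 25, duration_s = 20, seed = seed, ...)
}

# one hand-built recording: unit U1 with accelerometer + gyroscope
toy_recording <- function(N = 100L, rate = 25) {
  t <- seq_len(N)
  acc <- rbind(sin(t / 5), cos(t / 5), 1 + 0 * t)
  gyr <- rbind(cos(t / 3), 0.5 * sin(t / 3), 0.1 * t / N)
  recording("S01", "A01", list(
    sensor_channel_set("U1", "accelerometer", acc, rate),
    sensor_channel_set("U1", "gyroscope", gyr, rate)))
}

toy_dataset <- function(N = 100L, rate = 25) {
  oimotion_dataset(list(toy_recording(N, rate)),
                   list(rate = rate,
                        units = list(U1 = c("accelerometer", "gyroscope")),
                        subjects = "S01", activities = "A01"))
}

unit_scales <- function(types = c("accelerometer", "gyroscope")) {
  structure(setNames(rep(1, length(types)), types), class = "sensor_scales")
}

random_segment_blocks <- function(L = 40L, offset = c(9, 0, 0)) {
  list("U1/accelerometer" = matrix(rnorm(3 * L), 3) + offset,
       "U1/gyroscope" = matrix(rnorm(3 * L), 3))
}
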