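make_rec <- function(data, fs = 200, events = NULL) {
  if (is.null(events))
    events <- data.frame(sample = integer(), label = character())
  errp_recording(data, fs, paste0("CH", seq_len(nrow(data))), events = events)
}

test_that("band-pass removes DC and attenuates out-of-band tones", {
  fs <- 200
  n <- 10 * fs
  centre <- (4 * fs):(6 * fs)
  # pure DC is outside the 1-20 Hz band
  rec <- make_rec(matrix(1, 1, n), fs)
  out <- bandpass_filter(rec)
  expect_lt(max(abs(out$data[1, centre])), 1e-6)
  # 10 Hz passes at unit gain (two-pass Butterworth magnitude oracle)
  tone <- function(f) sin(2 * pi * f * seq_len(n) / fs)
  flt <- signal::butter(4, c(1, 20) / (fs / 2), type = "pass")
  gain <- function(f) {  # |H(f)|^2: transfer function evaluated on the unit circle
    z <- exp(-1i * 2 * pi * f / fs)
    Mod(sum(flt$b * z^(seq_along(flt$b) - 1)) /
        sum(flt$a * z^(seq_along(flt$a) - 1)))^2
  }
  amp10 <- sqrt(2) * sd(bandpass_filter(make_rec(t(tone(10))))$data[1, centre])
  expect_lt(abs(amp10 - 1), 0.05)
  expect_lt(abs(amp10 - gain(10)), 0.02)
  # 50 Hz is strongly attenuated
  amp50 <- sqrt(2) * sd(bandpass_filter(make_rec(t(tone(50))))$data[1, centre])
  expect_lt(amp50, 0.1)
  expect_lt(abs(amp50 - gain(50)), 0.02)
})

test_that("filtering is linear", {
  set.seed(1)
  x <- rnorm(600); y <- rnorm(600)
  f <- function(v) bandpass_filter(make_rec(t(v)))$data[1, ]
  lhs <- f(2.5 * x - 1.3 * y)
  rhs <- 2.5 * f(x) - 1.3 * f(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(rhs)), 1e-9)
})

test_that("band edges outside (0, Nyquist) are rejected", {
  rec <- make_rec(matrix(rnorm(400), 2, 200))
  expect_error(bandpass_filter(rec, 0, 20), "band edges")
  expect_error(bandpass_filter(rec, 1, 150), "band edges")
  expect_error(bandpass_filter(rec, 30, 20), "band edges")
})

test_that("common average reference has its defining properties", {
  set.seed(2)
  X <- matrix(rnorm(5 * 100), 5, 100)
  rec <- make_rec(X)
  out <- common_average_reference(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-12)          # zero mean per sample
  expect_equal(common_average_reference(out)$data, out$data)  # idempotent
  # identical channels cancel completely
  same <- make_rec(matrix(rep(rnorm(50), each = 3), 3, 50))
  expect_equal(max(abs(common_average_reference(same)$data)), 0)
  # an antisymmetric pair is already referenced
  a <- rnorm(80)
  pair <- make_rec(rbind(a, -a))
  expect_equal(common_average_reference(pair)$data, pair$data,
               ignore_attr = TRUE)
  expect_error(common_average_reference(make_rec(matrix(1, 1, 10))),
               "at least 2 channels")
})

test_that("epoch extraction slices 161 samples and preserves order and values", {
  set.seed(3)
  X <- matrix(rnorm(3 * 1200), 3, 1200)
  ev <- data.frame(sample = c(100, 400, 700),
                   label = c("positive", "negative", "positive"))
  rec <- make_rec(X, events = ev)
  eps <- extract_epochs(rec)
  expect_length(eps$epochs, 3)
  expect_identical(ncol(eps$epochs[[1]]), 161L)
  expect_identical(eps$labels, ev$label)
  # pure slicing: values are untouched
  expect_identical(eps$epochs[[2]], X[, 440:600])
})

test_that("events too close to the recording end are dropped with a warning", {
  X <- matrix(rnorm(2 * 500), 2, 500)
  ev <- data.frame(sample = c(100, 451),  # second needs samples up to 651
                   label = c("positive", "negative"))
  rec <- make_rec(X, events = ev)
  expect_warning(eps <- extract_epochs(rec), "dropped")
  expect_length(eps$epochs, 1)
  expect_identical(eps$labels, "positive")
  ev_all_bad <- data.frame(sample = 490, label = "positive")
  expect_warning(
    expect_error(extract_epochs(make_rec(X, events = ev_all_bad)), "no event"),
    "dropped")
})

test_that("the window sample count follows the inclusive-endpoint rule", {
  expect_identical(epoch_window(200, 1000, 200)$n_samples, 161L)
  expect_identical(epoch_window(0, 500, 100)$n_samples, 51L)
  expect_error(epoch_window(500, 200), "start_ms")
})

test_that("the artifact hook slots into the preprocessing chain", {
  cfg <- small_sim(epochs_per_subject = 5, channels = CH4, seed = 5)
  rec <- simulate_session(cfg)$S01
  seen <- FALSE
  hook <- function(r) { seen <<- TRUE; r }
  eps <- preprocess_session(rec, artifact_hook = hook)
  expect_true(seen)
  expect_length(eps$epochs, 5)
  expect_error(preprocess_session(rec, artifact_hook = function(r) 42),
               "must return")
})
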