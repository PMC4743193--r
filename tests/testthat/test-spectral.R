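test_that("a monotonic ramp yields no IMFs and is its own residue", {
  x <- seq(0, 5, length.out = 50)
  d <- emd(x)
  expect_identical(d$n_imfs, 0L)
  expect_equal(d$residue, x)
})

test_that("IMFs plus residue reconstruct the input (sifting identity)", {
  set.seed(1)
  for (rep in 1:20) {
    x <- cumsum(rnorm(161))
    d <- emd(x)
    recon <- Reduce(`+`, d$imfs, accumulate = FALSE) + d$residue
    expect_lt(max(abs(recon - x)) / max(abs(x)), 1e-9)
  }
})

test_that("a two-tone mixture separates, fast component first", {
  t <- (0:159) / 200
  x <- sin(2 * pi * 25 * t) + sin(2 * pi * 5 * t)
  d <- emd(x)
  expect_gte(d$n_imfs, 2)
  centre <- 41:120
  expect_gt(cor(d$imfs[[1]][centre], sin(2 * pi * 25 * t)[centre]), 0.9)
  expect_gt(cor((d$imfs[[2]] + d$residue)[centre],
                sin(2 * pi * 5 * t)[centre]), 0.9)
})

test_that("a pure tone is a single dominant IMF", {
  t <- (0:399) / 200
  x <- sin(2 * pi * 12 * t)
  d <- emd(x)
  energies <- vapply(d$imfs, function(c) sum(c^2), numeric(1))
  expect_gte(energies[1] / sum(energies, sum(d$residue^2)), 0.99)
})

test_that("non-finite input is fatal", {
  expect_error(emd(c(rnorm(30), NA)), "non-finite")
  expect_error(emd(rnorm(5)), "at least 8")
})

test_that("analytic signal of a pure tone has the closed-form amplitude and frequency", {
  fs <- 200
  t <- (0:399) / fs
  h <- hilbert_analytic(sin(2 * pi * 10 * t), fs)
  interior <- 41:360
  expect_lt(max(abs(h$amplitude[interior] - 1)), 0.02)
  expect_lt(max(abs(h$inst_frequency[interior] / (2 * pi) - 10)) / 10, 0.02)
  # amplitude identity a^2 = c^2 + H{c}^2
  expect_lt(max(abs(h$amplitude^2 -
                    (Re(h$analytic)^2 + Im(h$analytic)^2))), 1e-9)
  expect_equal(hilbert_analytic(rep(0, 64), fs)$amplitude, rep(0, 64))
})

test_that("the amplitude tracks a modulation envelope", {
  fs <- 200
  t <- (0:799) / fs
  env <- 1 + 0.5 * sin(2 * pi * 1 * t)
  h <- hilbert_analytic(env * sin(2 * pi * 20 * t), fs)
  interior <- 81:720
  expect_lt(max(abs(h$amplitude[interior] - env[interior]) / env[interior]),
            0.05)
})

test_that("spectral features are a 12-vector with unit relative energy", {
  set.seed(2)
  x <- cumsum(rnorm(161))
  f <- suppressWarnings(spectral_feature(x, 200))
  expect_length(f, 12)
  expect_named(f, c(sprintf("E_%d", 1:3), sprintf("Phi_%d", 1:3),
                    sprintf("MS_%d", 1:3), sprintf("CV_%d", 1:3)))
  expect_equal(sum(f[1:3]), 1, tolerance = 1e-9)
  expect_true(all(f[1:3] >= 0 & f[1:3] <= 1))
})

test_that("mean slope telescopes and CV matches the direct statistics", {
  set.seed(3)
  t <- (0:160) / 200
  x <- sin(2 * pi * 22 * t) + 0.7 * sin(2 * pi * 6 * t) + 0.1 * rnorm(161)
  d <- emd(x)
  f <- suppressWarnings(spectral_feature(x, 200))
  for (i in seq_len(min(3, d$n_imfs))) {
    ci <- d$imfs[[i]]
    expect_equal(unname(f[paste0("MS_", i)]),
                 (ci[161] - ci[1]) * 200 / 160, tolerance = 1e-10)
    expect_equal(unname(f[paste0("MS_", i)]), mean(diff(ci)) * 200,
                 tolerance = 1e-10)
    if (abs(mean(ci)) > 1e-12 * sd(ci))
      expect_equal(unname(f[paste0("CV_", i)]), sd(ci) / mean(ci),
                   tolerance = 1e-10)
  }
})

test_that("E and CV are scale invariant while MS scales linearly", {
  set.seed(4)
  t <- (0:160) / 200
  x <- sin(2 * pi * 22 * t) + 0.7 * sin(2 * pi * 6 * t) + 0.1 * rnorm(161)
  f1 <- suppressWarnings(spectral_feature(x, 200))
  f5 <- suppressWarnings(spectral_feature(5 * x, 200))
  expect_equal(f5[1:3], f1[1:3], tolerance = 1e-8)          # E
  expect_equal(f5[10:12], f1[10:12], tolerance = 1e-8)      # CV
  expect_equal(f5[7:9], 5 * f1[7:9], tolerance = 1e-8)      # MS
})

test_that("missing IMF slots are zero-filled with a warning", {
  t <- (0:160) / 200
  x <- sin(2 * pi * 5 * t) + 10 * t  # one IMF, then a monotone residue
  expect_identical(emd(x)$n_imfs, 1L)
  expect_warning(f <- spectral_feature(x, 200), "fewer than 3 IMFs")
  expect_true(all(f[c("E_2", "E_3", "MS_3", "CV_3")] == 0))
  expect_equal(sum(f[1:3]), 1, tolerance = 1e-9)
})

test_that("mean frequency can be reported in Hz", {
  t <- (0:399) / 200
  x <- sin(2 * pi * 12 * t)
  f <- suppressWarnings(spectral_feature(x, 200, freq_unit = "hz"))
  expect_lt(abs(f[["Phi_1"]] - 12), 0.5)
  frad <- suppressWarnings(spectral_feature(x, 200))
  expect_equal(frad[["Phi_1"]] / (2 * pi), f[["Phi_1"]], tolerance = 1e-9)
})
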