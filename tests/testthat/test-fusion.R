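# a small but realistic training set shared by several tests
fusion_fixture <- function() {
  if (is.null(.fusion_cache$model)) {
    tr <- simulate_epochs(small_sim(n_subjects = 2, epochs_per_subject = 50,
                                    channels = CH6, snr = 5, seed = 11))
    te <- simulate_epochs(small_sim(n_subjects = 1, epochs_per_subject = 50,
                                    channels = CH6, snr = 5, seed = 77))
    .fusion_cache$train <- tr
    .fusion_cache$test <- te
    .fusion_cache$model <- suppressWarnings(errp_fusion(tr, seed = 1))
  }
  .fusion_cache
}
.fusion_cache <- new.env()

test_that("the fitted model has the specified cascade structure", {
  fx <- fusion_fixture()
  m <- fx$model
  expect_s3_class(m, "errp_fusion")
  expect_named(m$stage1, c("temporal", "spectral", "spatial"))
  for (d in names(m$stage1)) expect_length(m$stage1[[d]], 6)
  expect_identical(m$stage1$temporal[[1]]$d, 164L)
  expect_identical(m$stage1$spectral[[1]]$d, 12L)
  expect_identical(m$stage1$spatial[[1]]$d, 161L)
  expect_length(m$combiners, 7)
  # the final classifier sees exactly the 3 per-domain posteriors
  expect_identical(m$combiners[["temporal+spectral+spatial"]]$d, 3L)
})

test_that("level-2 and level-3 representations are posteriors of the right shape", {
  fx <- fusion_fixture()
  l2 <- suppressWarnings(stage1_posteriors(fx$model, fx$test))
  expect_named(l2, c("temporal", "spectral", "spatial"))
  for (d in names(l2)) {
    expect_identical(dim(l2[[d]]), c(50L, 6L))
    expect_true(all(l2[[d]] >= 0 & l2[[d]] <= 1))
  }
  l3 <- suppressWarnings(level3_features(fx$model, fx$test))
  expect_identical(dim(l3), c(50L, 3L))
  expect_true(all(l3 >= 0 & l3 <= 1))
  # identical epochs map to identical representations
  dup <- subset_epochs(fx$test, c(1, 1))
  l2d <- suppressWarnings(stage1_posteriors(fx$model, dup))
  for (d in names(l2d)) expect_identical(l2d[[d]][1, ], l2d[[d]][2, ])
})

test_that("training and prediction are deterministic under the master seed", {
  fx <- fusion_fixture()
  m2 <- suppressWarnings(errp_fusion(fx$train, seed = 1))
  expect_identical(suppressWarnings(predict(m2, fx$test)),
                   suppressWarnings(predict(fx$model, fx$test)))
})

test_that("a strongly planted signal is classified near-perfectly", {
  fx <- fusion_fixture()
  sc <- suppressWarnings(predict(fx$model, fx$test))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(roc_auc(sc, fx$test$labels)$auc, 0.95)
  lab <- suppressWarnings(predict(fx$model, fx$test, type = "label"))
  expect_identical(lab, ifelse(sc >= 0.5, "positive", "negative"))
  both <- suppressWarnings(predict(fx$model, fx$test, type = "both"))
  expect_identical(both$score, sc)
})

test_that("the model round-trips through CSV serialization with identical predictions", {
  fx <- fusion_fixture()
  dir <- withr::local_tempdir()
  write_errp_model(fx$model, dir)
  expect_true(file.exists(file.path(dir, "metadata.txt")))
  m2 <- read_errp_model(dir)
  expect_identical(suppressWarnings(predict(m2, fx$test)),
                   suppressWarnings(predict(fx$model, fx$test)))
  for (d in c("temporal", "spectral", "spatial"))
    expect_identical(suppressWarnings(predict(m2, fx$test, domains = d)),
                     suppressWarnings(predict(fx$model, fx$test, domains = d)))
})

test_that("channel mismatches and unlabeled training input are fatal", {
  fx <- fusion_fixture()
  expect_error(suppressWarnings(predict(fx$model, subset_channels(fx$test, CH4))),
               "channel labels")
  tr <- fx$train
  tr$labels[3] <- NA
  expect_error(errp_fusion(tr), "labeled")
})

test_that("pipeline AUC is non-decreasing in the planted signal-to-noise ratio", {
  auc <- vapply(c(0, 1, 3, 5), function(s) {
    eps <- simulate_epochs(sim_config(n_subjects = 4, epochs_per_subject = 100,
                                      n_channels = 8, channel_labels = CH8,
                                      snr = s, seed = 21))
    tr <- subset_epochs(eps, eps$subjects %in% c("S01", "S02"))
    te <- subset_epochs(eps, !eps$subjects %in% c("S01", "S02"))
    m <- suppressWarnings(errp_fusion(tr, seed = 5))
    roc_auc(suppressWarnings(predict(m, te)), te$labels)$auc
  }, numeric(1))
  expect_true(all(diff(auc) > -0.03))
  expect_gt(auc[4], 0.9)
})
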