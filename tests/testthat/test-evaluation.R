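test_that("confusion cells match direct enumeration and sum to 100%", {
  # perfect scores, balanced classes
  cm <- confusion_matrix(rep(c(1, 0), each = 5),
                         rep(c("positive", "negative"), each = 5))
  expect_equal(cm$tp_pct, 50)
  expect_equal(cm$tn_pct, 50)
  expect_equal(cm$accuracy_pct, 100)
  # everything called positive on a 70/30 split
  cm2 <- confusion_matrix(rep(1, 10),
                          rep(c("positive", "negative"), c(7, 3)))
  expect_equal(cm2$tp_pct, 70)
  expect_equal(cm2$fp_pct, 30)
  expect_equal(cm2$accuracy_pct, 70)
  # random fixture against the enumeration oracle
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(20:60, 1)
    sc <- round(runif(n), 2)
    lb <- sample(c("positive", "negative"), n, replace = TRUE)
    cm3 <- confusion_matrix(sc, lb)
    oracle <- count_cells(sc, lb)
    expect_equal(c(tn = cm3$tn_pct, fp = cm3$fp_pct,
                   fn = cm3$fn_pct, tp = cm3$tp_pct), oracle,
                 tolerance = 1e-12)
    expect_equal(cm3$tn_pct + cm3$fp_pct + cm3$fn_pct + cm3$tp_pct, 100,
                 tolerance = 1e-9)
    # permutation invariance
    p <- sample(n)
    cm4 <- confusion_matrix(sc[p], lb[p])
    expect_identical(cm4$counts, cm3$counts)
  }
  expect_error(confusion_matrix(numeric(0), character(0)), "empty")
})

test_that("ROC endpoints, trivial cases and the pair-counting oracle agree", {
  lab <- rep(c("positive", "negative"), each = 4)
  perfect <- roc_auc(c(.9, .8, .9, .7, .1, .2, .3, .2), lab)
  expect_equal(perfect$auc, 1)
  ties <- roc_auc(rep(0.5, 8), lab)
  expect_equal(ties$auc, 0.5)
  set.seed(2)
  for (rep in 1:5) {
    n <- sample(15:40, 1)
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # deliberate ties
    lb <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    r <- roc_auc(sc, lb)
    expect_lt(abs(r$auc - auc_pairs(sc, lb)), 1e-12)
    # curve properties
    expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
    expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
    expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
    # invariance under a strictly increasing transform
    expect_equal(roc_auc(plogis(5 * sc - 2), lb)$auc, r$auc,
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(c(.1, .2), c("positive", "positive")), "both classes")
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  sc <- runif(60)
  lb <- sample(c("positive", "negative"), 60, replace = TRUE)
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = lb, predictor = sc, levels = c("negative", "positive"),
    direction = "<")))
  expect_equal(roc_auc(sc, lb)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("per-subject AUC table has the seven-combination layout", {
  tr <- simulate_epochs(small_sim(n_subjects = 2, epochs_per_subject = 40,
                                  channels = CH4, snr = 5, seed = 31))
  te <- simulate_epochs(small_sim(n_subjects = 3, epochs_per_subject = 40,
                                  channels = CH4, snr = 5, seed = 32))
  m <- suppressWarnings(errp_fusion(tr, seed = 2))
  tab <- suppressWarnings(per_subject_auc(m, te))
  expect_identical(colnames(tab),
                   c("temporal", "spectral", "spatial",
                     "temporal+spectral", "temporal+spatial",
                     "spectral+spatial", "temporal+spectral+spatial"))
  expect_identical(rownames(tab), c("S01", "S02", "S03", "Average"))
  expect_equal(unlist(tab["Average", ]),
               colMeans(as.matrix(tab[1:3, ])), tolerance = 1e-12)
  # one subject: the average equals that subject's AUC
  te1 <- subset_epochs(te, te$subjects == "S01")
  tab1 <- suppressWarnings(per_subject_auc(m, te1))
  expect_equal(unlist(tab1["Average", ]), unlist(tab1["S01", ]),
               tolerance = 1e-12)
  # subjects with a single class are skipped with a warning
  te_bad <- te
  te_bad$labels[te_bad$subjects == "S02"] <- "positive"
  w <- capture_warnings(tab2 <- per_subject_auc(m, te_bad))
  expect_true(any(grepl("S02", w)))
  expect_false("S02" %in% rownames(tab2))
})

test_that("electrode ablation recovers the planted topography", {
  chans <- c("FCz", "Cz", "P8", "O1")
  tr <- simulate_epochs(small_sim(n_subjects = 2, epochs_per_subject = 60,
                                  channels = chans, snr = 3, seed = 41))
  te <- simulate_epochs(small_sim(n_subjects = 1, epochs_per_subject = 60,
                                  channels = chans, snr = 3, seed = 42))
  ab <- suppressWarnings(electrode_ablation(tr, te, seed = 3))
  expect_named(ab$single, chans)
  # fronto-central sites beat the far occipital site by a clear margin
  expect_gt(ab$single[["FCz"]], ab$single[["O1"]] + 0.1)
  expect_gt(ab$single[["Cz"]], ab$single[["O1"]] + 0.1)
  # the full cumulative prefix equals a direct full-montage fit
  full <- suppressWarnings(errp_fusion(tr, seed = 3))
  full_auc <- roc_auc(suppressWarnings(predict(full, te)), te$labels)$auc
  expect_equal(unname(ab$cumulative[[length(chans)]]), full_auc,
               tolerance = 1e-12)
})

test_that("single-electrode AUC is near chance on signal-free data", {
  chans <- c("FCz", "P8")
  tr <- simulate_epochs(small_sim(n_subjects = 2, epochs_per_subject = 80,
                                  channels = chans, snr = 0, seed = 51))
  te <- simulate_epochs(small_sim(n_subjects = 2, epochs_per_subject = 80,
                                  channels = chans, snr = 0, seed = 52))
  ab <- suppressWarnings(electrode_ablation(tr, te, electrodes = "FCz",
                                            cumulative = FALSE, seed = 4))
  expect_lt(abs(ab$single[["FCz"]] - 0.5), 0.08)
})
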