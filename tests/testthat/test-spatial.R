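test_that("class covariances are unit-trace means of normalized outer products", {
  eps <- toy_epochs(n = 4, channels = CH4, ns = 40, seed = 1)
  cov <- class_covariances(eps)
  expect_equal(sum(diag(cov$positive)), 1, tolerance = 1e-10)
  expect_equal(sum(diag(cov$negative)), 1, tolerance = 1e-10)
  # brute-force oracle
  for (lab in c("positive", "negative")) {
    idx <- which(eps$labels == lab)
    mats <- lapply(eps$epochs[idx], function(X) {
      R <- X %*% t(X)
      R / sum(diag(R))
    })
    expect_equal(cov[[lab]], Reduce(`+`, mats) / length(mats),
                 tolerance = 1e-12)
  }
  # single epoch per class
  one <- subset_epochs(eps, 1:2)
  cov1 <- class_covariances(one)
  X <- one$epochs[[1]]
  expect_equal(cov1$positive, X %*% t(X) / sum(X^2), tolerance = 1e-12)
})

test_that("zero-energy epochs are fatal with their index", {
  eps <- toy_epochs(n = 4, channels = CH2, ns = 20, seed = 2)
  eps$epochs[[3]][] <- 0
  expect_error(class_covariances(eps), "epoch 3")
})

test_that("identical class covariances give all eigenvalues 1/2", {
  n <- 4
  R <- random_spd(n, 0.5, seed = 3)
  bank <- fit_csp(list(positive = R, negative = R,
                       channel_labels = paste0("c", 1:n)))
  expect_equal(bank$lambda_p, rep(0.5, n), tolerance = 1e-10)
})

test_that("the 2-channel toy recovers the hand-computed filter", {
  # R_p + R_n = I, so whitening is the identity and the common eigenvectors
  # are the coordinate axes: lambda_p = (0.8, 0.2), first filter = channel 1
  bank <- fit_csp(list(positive = diag(c(0.8, 0.2)),
                       negative = diag(c(0.2, 0.8)),
                       channel_labels = CH2))
  expect_equal(bank$lambda_p, c(0.8, 0.2), tolerance = 1e-12)
  expect_equal(abs(bank$W), diag(2), tolerance = 1e-12)
})

test_that("CSP algebra holds on random SPD pairs", {
  for (s in 1:5) {
    n <- 6
    Rp <- random_spd(n, 0.5, seed = 10 + s)
    Rn <- random_spd(n, 0.5)
    bank <- fit_csp(list(positive = Rp, negative = Rn,
                         channel_labels = paste0("c", 1:n)))
    C <- Rp + Rn
    expect_lt(max(abs(bank$P %*% C %*% t(bank$P) - diag(n))), 1e-8)
    expect_lt(max(abs(bank$lambda_p + bank$lambda_n - 1)), 1e-8)
    expect_lt(max(abs(bank$W %*% C %*% t(bank$W) - diag(n))), 1e-8)
    # simultaneous diagonalization of both class matrices
    Dp <- bank$W %*% Rp %*% t(bank$W)
    Dn <- bank$W %*% Rn %*% t(bank$W)
    expect_lt(max(abs(Dp - diag(diag(Dp)))), 1e-8)
    expect_lt(max(abs(Dn - diag(diag(Dn)))), 1e-8)
    expect_equal(diag(Dp), bank$lambda_p, tolerance = 1e-8)
    # rows ordered by lambda_p, descending
    expect_true(all(diff(bank$lambda_p) <= 1e-12))
  }
})

test_that("projection is the plain matrix product with all filters kept", {
  eps <- toy_epochs(n = 10, channels = CH4, ns = 161, seed = 4)
  bank <- fit_csp(class_covariances(eps))
  Y <- csp_project(eps$epochs[[1]], bank)
  expect_identical(dim(Y), c(4L, 161L))
  expect_equal(Y, bank$W %*% eps$epochs[[1]], tolerance = 1e-12)
  expect_equal(csp_project(2.5 * eps$epochs[[1]], bank), 2.5 * Y,
               tolerance = 1e-12)
  # identity bank passes the epoch through
  eye <- structure(list(W = diag(4), channel_labels = CH4), class = "errp_csp")
  expect_identical(csp_project(eps$epochs[[1]], eye), eps$epochs[[1]])
  expect_error(csp_project(eps$epochs[[1]][1:2, ], bank), "channels")
})

# epochs whose classes differ only in the variance of one spatial pattern
planted_pattern_epochs <- function(n = 60, nch = 6, ns = 120, gain = 3,
                                   seed = 5) {
  set.seed(seed)
  pat <- rnorm(nch); pat <- pat / sqrt(sum(pat^2))
  labels <- rep(c("positive", "negative"), length.out = n)
  eps <- lapply(labels, function(lab) {
    E <- matrix(rnorm(nch * ns), nch, ns)
    if (lab == "positive") E <- E + pat %*% t(rnorm(ns, 0, gain))
    E
  })
  list(set = errp_epochs(eps, labels, "S01", paste0("c", 1:nch), 200),
       pattern = pat)
}

test_that("the top filter recovers a planted spatial pattern", {
  pp <- planted_pattern_epochs(gain = 3)
  bank <- fit_csp(class_covariances(pp$set))
  w1 <- bank$W[1, ]
  cosine <- abs(sum(w1 * pp$pattern)) /
    sqrt(sum(w1^2) * sum(pp$pattern^2))
  expect_gt(cosine, 0.95)
})

test_that("projection variances order by class as CSP requires", {
  pp <- planted_pattern_epochs(gain = 2, seed = 6)
  bank <- fit_csp(class_covariances(pp$set))
  proj_var <- function(lab, row) {
    idx <- which(pp$set$labels == lab)
    mean(vapply(pp$set$epochs[idx], function(X) {
      Xn <- X / sqrt(sum(X^2))  # match the trace normalization
      var(drop(bank$W[row, ] %*% Xn))
    }, numeric(1)))
  }
  n <- nrow(bank$W)
  expect_gt(proj_var("positive", 1), proj_var("negative", 1))
  expect_lt(proj_var("positive", n), proj_var("negative", n))
})
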