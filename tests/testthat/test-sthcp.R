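# STHCP decoder: class covariances, CSP, temporal PCA, LDA, grid search.

test_that("class covariances are trace-normalised, symmetric, and match a naive oracle", {
  # single identity trial per class: Y I2 -> (I %*% I) / trace = I/2
  ep <- epoch_set(array(c(diag(2), diag(2)), dim = c(2, 2, 2)),
                  c(1L, 0L), c(0, 0.01), c("a", "b"), 100)
  # array filling: build explicitly
  dat <- array(0, dim = c(2, 2, 2))
  dat[1, , ] <- diag(2); dat[2, , ] <- diag(2)
  ep <- epoch_set(dat, c(1L, 0L), c(0, 0.01), c("a", "b"), 100)
  covs <- class_covariances(ep)
  expect_equal(covs$target, diag(2) / 2)
  expect_equal(covs$nontarget, diag(2) / 2)

  withr::with_seed(10, {
    dat <- array(rnorm(20 * 4 * 30), dim = c(20, 4, 30))
    labels <- rep(c(1L, 0L), 10)
  })
  ep <- epoch_set(dat, labels, seq(0, by = 0.01, length.out = 30),
                  sprintf("c%d", 1:4), 100)
  covs <- class_covariances(ep)
  expect_lt(max(abs(covs$target - t(covs$target))), 1e-12)
  # naive per-trial loop oracle
  for (cls in c(1L, 0L)) {
    acc <- matrix(0, 4, 4)
    for (i in which(labels == cls)) {
      Y <- dat[i, , ]
      acc <- acc + (Y %*% t(Y)) / sum(diag(Y %*% t(Y)))
    }
    got <- if (cls == 1L) covs$target else covs$nontarget
    expect_equal(got, acc / 10, tolerance = 1e-12)
  }
})

test_that("CSP recovers the closed-form eigenstructure of diagonal covariances", {
  bank <- fit_csp(diag(c(4, 1)), diag(c(1, 4)), 2, shrinkage = 0)
  expect_equal(sort(bank$eigenvalues), c(0.25, 4), tolerance = 1e-10)
  # filters align with the coordinate axes: one entry ~1, the other ~0
  for (j in 1:2) {
    w <- abs(bank$W[, j]) / sqrt(sum(bank$W[, j]^2))
    expect_lt(abs(max(w) - 1), 1e-8)
    expect_lt(min(w), 1e-8)
  }
  # identical classes -> all generalized eigenvalues 1
  S <- crossprod(matrix(rnorm(25), 5)) + diag(5)
  bank2 <- fit_csp(S, S, 4, shrinkage = 0)
  expect_equal(bank2$eigenvalues, rep(1, 4), tolerance = 1e-10)
})

test_that("CSP filters satisfy the generalized eigen equation and diagonalize both classes", {
  withr::with_seed(5, {
    A <- crossprod(matrix(rnorm(36), 6)) / 6 + diag(6) * 0.1
    B <- crossprod(matrix(rnorm(36), 6)) / 6 + diag(6) * 0.1
  })
  bank <- fit_csp(A, B, 6, shrinkage = 0)
  for (j in 1:6) {
    w <- bank$W[, j]; lam <- bank$eigenvalues[j]
    expect_lt(max(abs(A %*% w - lam * (B %*% w))), 1e-8)
    # variance ratio equals the eigenvalue
    expect_equal(drop(t(w) %*% A %*% w / (t(w) %*% B %*% w)), lam,
                 tolerance = 1e-10)
  }
  for (S in list(A, B)) {
    D <- t(bank$W) %*% S %*% bank$W
    expect_lt(max(abs(D - diag(diag(D)))), 1e-8)
  }
  # eigenvalue order alternates ends of the spectrum
  lam <- bank$eigenvalues
  expect_equal(which.max(lam), 1L)
  expect_equal(which.min(lam), 2L)
})

test_that("apply_csp is the per-trial left multiplication by t(W)", {
  withr::with_seed(6, {
    dat <- array(rnorm(8 * 4 * 20), dim = c(8, 4, 20))
  })
  ep <- epoch_set(dat, rep(c(1L, 0L), 4),
                  seq(0, by = 0.01, length.out = 20), sprintf("c%d", 1:4), 100)
  idbank <- structure(list(W = diag(4), eigenvalues = rep(1, 4),
                           n_filters = 4L), class = "csp_filters")
  out <- apply_csp(ep, idbank)
  expect_equal(out$data, ep$data, ignore_attr = TRUE)

  covs <- class_covariances(ep)
  bank <- fit_csp(covs$target, covs$nontarget, 2)
  out2 <- apply_csp(ep, bank)
  expect_equal(dim(out2)[2], 2)
  for (i in c(1, 5)) {
    expect_equal(out2$data[i, , ], t(bank$W) %*% ep$data[i, , ],
                 ignore_attr = TRUE)
  }
  # linearity
  ep2 <- ep; ep2$data <- 2 * ep$data
  expect_equal(apply_csp(ep2, bank)$data, 2 * out2$data)
  # dimension mismatch names both dimensions
  ep3 <- tiny_epochs(n_trials = 4, n_channels = 6)
  expect_error(apply_csp(ep3, bank), regexp = "4.*6|6.*4",
               class = "dpifuse_format_error")
})

test_that("temporal PCA recovers rank-1 structure and matches an SVD oracle", {
  v <- sin(seq(0, 2 * pi, length.out = 25)); v <- v / sqrt(sum(v^2))
  withr::with_seed(7, {
    amps <- rnorm(12)
    dat <- array(0, dim = c(12, 2, 25))
    for (i in 1:12) for (c in 1:2) dat[i, c, ] <- amps[i] * v
  })
  ep <- epoch_set(dat, rep(c(1L, 0L), 6),
                  seq(0, by = 0.01, length.out = 25), c("a", "b"), 100)
  proj <- fit_temporal_pca(ep, 2)
  x1 <- proj$projections[[1]][, 1]
  expect_gt(abs(sum(x1 * v)), 1 - 1e-9)
  ev <- proj$eigenvalues[[1]]
  expect_gt(ev[1] / sum(pmax(ev, 0)), 0.999)

  withr::with_seed(8, {
    dat <- array(rnorm(15 * 3 * 10), dim = c(15, 3, 10))
  })
  ep <- epoch_set(dat, rep(c(1L, 0L), length.out = 15),
                  seq(0, by = 0.01, length.out = 10), c("a", "b", "c"), 100)
  proj <- fit_temporal_pca(ep, 5)
  for (c in 1:3) {
    X <- proj$projections[[c]]
    expect_equal(crossprod(X), diag(5), tolerance = 1e-10)
    # explained variance fractions match a brute-force SVD oracle
    Yc <- scale(dat[, c, ], center = TRUE, scale = FALSE)
    sv <- svd(Yc)$d^2 / (15 - 1)
    expect_equal(proj$eigenvalues[[c]][1:5], sv[1:5], tolerance = 1e-10)
  }
  # K = samples preserves total variance
  proj_full <- fit_temporal_pca(ep, 10)
  feats <- extract_features(ep, proj_full)
  expect_equal(sum(feats^2), sum(ep$data^2), tolerance = 1e-9)
  expect_error(fit_temporal_pca(ep, 11), class = "dpifuse_config_error")
})

test_that("feature extraction concatenates per-channel projections", {
  ep <- tiny_epochs(n_trials = 10, n_channels = 3, n_samples = 12)
  proj <- fit_temporal_pca(ep, 4)
  feats <- extract_features(ep, proj)
  expect_equal(dim(feats), c(10, 12))
  # zero epoch -> zero features
  ep0 <- ep; ep0$data[1, , ] <- 0
  expect_equal(max(abs(extract_features(ep0, proj)[1, ])), 0)
  # delta projector picks out the first sample
  delta <- structure(list(projections = list(diag(12)[, 1, drop = FALSE]),
                          eigenvalues = list(1), means = matrix(0, 1, 12),
                          n_components = 1L), class = "temporal_pca")
  ep1 <- ep
  ep1$data <- ep$data[, 1, , drop = FALSE]
  ep1$channel_names <- "c1"
  expect_equal(drop(extract_features(ep1, delta)), ep$data[, 1, 1])
})

test_that("shrinkage LDA yields calibrated posteriors on symmetric toys", {
  withr::with_seed(9, {
    x <- matrix(c(rnorm(200, -1), rnorm(200, 1)), ncol = 1)
  })
  labels <- rep(c(0L, 1L), each = 200)
  cls <- fit_lda(x, labels)
  expect_equal(predict_posterior(cls, matrix(0, 1, 1)), 0.5,
               tolerance = 0.05, ignore_attr = TRUE)
  expect_gt(predict_posterior(cls, matrix(50, 1, 1)), 1 - 1e-6)

  # hand-chosen separable 2-d toy: all training posteriors on the right side
  toy <- rbind(c(0, 0), c(1, 0), c(0, 1), c(0.5, 0.5),
               c(3, 3), c(4, 3), c(3, 4), c(3.5, 3.5))
  toy_labels <- rep(c(0L, 1L), each = 4)
  cls2 <- fit_lda(toy, toy_labels)
  p <- predict_posterior(cls2, toy)
  expect_true(all((p > 0.5) == (toy_labels == 1L)))
})

test_that("shrinkage LDA agrees with an established reference at zero shrinkage", {
  skip_if_not_installed("MASS")
  withr::with_seed(12, {
    x <- matrix(rnorm(300 * 4), ncol = 4)
    labels <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(300) > 0)
  })
  cls <- fit_lda(x, labels, shrinkage = 0)
  ref <- MASS::lda(x, grouping = labels)
  p_ref <- predict(ref, x)$posterior[, "1"]
  p_got <- predict_posterior(cls, x)
  expect_equal(p_got, p_ref, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("grid search selects by validation AUC with documented tie-break", {
  ep <- tiny_epochs(n_trials = 80, n_channels = 6, n_samples = 30,
                    effect = 1.5, seed = 33)
  va <- tiny_epochs(n_trials = 40, n_channels = 6, n_samples = 30,
                    effect = 1.5, seed = 34)
  # single grid point is returned as-is
  m1 <- sthcp(ep, va, n_filters_grid = 3, n_components_grid = 2,
              feature_window_s = c(-0.1, 0.3))
  expect_identical(unname(m1$selected), c(3L, 2L))
  m <- sthcp(ep, va, n_filters_grid = c(2, 4), n_components_grid = c(1, 2, 3),
             feature_window_s = c(-0.1, 0.3))
  expect_s3_class(m, "sthcp")
  expect_equal(m$validation_auc, max(m$grid_auc, na.rm = TRUE))
  # selection = first maximum scanning smaller n_filters then smaller K
  flat <- which(t(m$grid_auc) >= m$validation_auc - 1e-12, arr.ind = TRUE)
  first <- flat[order(flat[, 2], flat[, 1]), , drop = FALSE][1, ]
  expect_identical(unname(m$selected),
                   c(c(2L, 4L)[first[2]], c(1L, 2L, 3L)[first[1]]))
  # prediction returns a valid score set over new data
  ts <- predict(m, tiny_epochs(n_trials = 30, n_channels = 6,
                               n_samples = 30, effect = 1.5, seed = 35))
  expect_s3_class(ts, "score_set")
  expect_true(all(ts$posteriors > 0 & ts$posteriors < 1))
  expect_error(sthcp(ep, va, n_filters_grid = integer(0)),
               class = "dpifuse_config_error")
})
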