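# BPA construction and the three fusers (DPI, NBF, DBF).

test_that("BPA substitutes the performance weights into the mass triple", {
  model <- constant_performance(g = 0.9, f = 0.8)
  m <- assign_bpa(0.7, model)
  expect_equal(unname(unclass(m)), c(0.63, 0.24, 0.13), tolerance = 1e-12)
  # uninformative source -> vacuous mass
  m0 <- assign_bpa(0.4, constant_performance(0, 0))
  expect_equal(unname(unclass(m0)), c(0, 0, 1))
  # fully reliable source -> no uncertainty
  m1 <- assign_bpa(0.3, constant_performance(1, 1))
  expect_equal(m1[["uncertain"]], 0)
  # vectorised form returns valid rows
  withr::with_seed(30, {
    M <- assign_bpa(runif(50), model)
  })
  expect_equal(rowSums(M), rep(1, 50), tolerance = 1e-12)
  expect_true(all(M >= 0))
})

test_that("a vacuous source leaves the informative source's ranking intact", {
  withr::with_seed(31, {
    sc1 <- score_set(runif(200), rbinom(200, 1, 0.3), source_id = "a")
  })
  sc2 <- score_set(rep(0.5, 200), sc1$labels, source_id = "b")
  res <- dpi_fuse(list(
    list(scores = sc1, model = constant_performance(0.9, 0.85)),
    list(scores = sc2, model = constant_performance(0, 0))))
  expect_equal(order(res$p_pig_target), order(sc1$posteriors))
  expect_equal(res$n_total_conflict, 0)
  # every fused mass is a valid mass function
  expect_equal(rowSums(res$mass), rep(1, 200), tolerance = 1e-10)
  expect_true(all(res$mass >= -1e-12))
})

test_that("two agreeing confident sources reproduce their thresholded predictions", {
  labels <- rep(c(1L, 0L), each = 25)
  post <- ifelse(labels == 1L, 0.95, 0.05)
  s1 <- score_set(post, labels, source_id = "a")
  s2 <- score_set(post, labels, source_id = "b")
  perf <- constant_performance(0.98, 0.98)
  res <- dpi_fuse(list(list(scores = s1, model = perf),
                       list(scores = s2, model = perf)),
                  decision_threshold = 0.5)
  expect_identical(res$predicted, as.integer(post > 0.5))
})

test_that("misaligned trial ids are reported with the first mismatch", {
  s1 <- score_set(c(0.1, 0.9), c(0L, 1L), trial_ids = c("a", "b"))
  s2 <- score_set(c(0.2, 0.8), c(0L, 1L), trial_ids = c("a", "c"))
  expect_error(dpi_fuse(list(list(scores = s1, model = constant_performance(1, 1)),
                             list(scores = s2, model = constant_performance(1, 1)))),
               regexp = "position 2", class = "dpifuse_validation_error")
})

test_that("naive Bayesian fusion follows its closed form", {
  labels <- c(0L, 1L, 0L, 1L)
  f <- function(p1, p2, prior = NULL) {
    s1 <- score_set(rep(p1, 4), labels, source_id = "a")
    s2 <- score_set(rep(p2, 4), labels, source_id = "b")
    nbf_fuse(list(s1, s2), prior_target = prior)$posteriors[1]
  }
  expect_equal(f(0.5, 0.5, 0.5), 0.5, tolerance = 1e-9)
  expect_equal(f(0.9, 0.9, 0.5), 0.81 / (0.81 + 0.01), tolerance = 1e-9)
  # an everywhere-0.5 source preserves the other source's ranking
  withr::with_seed(32, {
    s1 <- score_set(runif(100), rbinom(100, 1, 0.3), source_id = "a")
  })
  s2 <- score_set(rep(0.5, 100), s1$labels, source_id = "b")
  fused <- nbf_fuse(list(s1, s2), prior_target = 0.5)
  expect_equal(order(fused$posteriors), order(s1$posteriors))
})

test_that("DBF assigns precision/recall masses with valid clipping", {
  # perfect detector: precision = recall = 1 at its operating point (any
  # threshold inside the class separation gap)
  labels <- rep(c(1L, 0L), each = 100)
  post <- ifelse(labels == 1L, 0.9, 0.1)
  withr::with_seed(33, {
    post <- post + runif(200, -0.05, 0.05)
  })
  sc <- score_set(post, labels, source_id = "perfect")
  pr <- dbf_model(sc)
  mid <- which.min(abs(pr$threshold_grid - 0.5))
  expect_gt(pr$precision[mid], 0.99)
  expect_gt(pr$recall[mid], 0.99)
  res <- dbf_fuse(list(list(scores = sc, model = pr),
                       list(scores = sc, model = pr)))
  expect_equal(rowSums(res$mass), rep(1, 200), tolerance = 1e-10)
  expect_true(all(res$mass >= -1e-12))

  # chance detector at 25% prevalence: precision near prevalence
  withr::with_seed(34, {
    ch <- score_set(runif(2000, 0.2, 0.3), rbinom(2000, 1, 0.25),
                    source_id = "chance")
  })
  pr_ch <- dbf_model(ch)
  mid <- which.min(abs(pr_ch$threshold_grid - 0.25))
  expect_lt(abs(pr_ch$precision[mid] - 0.25), 0.05)
})

test_that("under conflicting source quality DPI usually beats both baselines", {
  wins_dbf <- 0; wins_nbf <- 0; conflicts <- 0
  n_seeds <- 20
  labels <- rep(c(1L, 0L), c(250, 750))
  for (s in 1:n_seeds) {
    weak <- simulate_detector_scores(labels,
      detector_sim_config(d_prime = d_prime_for_auc(0.75), seed = 2 * s),
      source_id = "weak")
    strong <- simulate_detector_scores(labels,
      detector_sim_config(d_prime = d_prime_for_auc(0.9), seed = 2 * s + 1),
      source_id = "strong")
    ex <- run_fusion_experiment(list(weak, strong), seed = s)
    conflicts <- conflicts + ex$conflict_flag
    if (ex$mean["DPI", "auc"] >= ex$mean["DBF", "auc"]) wins_dbf <- wins_dbf + 1
    if (ex$mean["DPI", "auc"] >= ex$mean["NBF", "auc"]) wins_nbf <- wins_nbf + 1
  }
  expect_gt(conflicts, n_seeds / 2)   # the regime really is conflicting
  expect_gt(wins_dbf, n_seeds / 2)
  expect_gt(wins_nbf, n_seeds / 2)
})
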