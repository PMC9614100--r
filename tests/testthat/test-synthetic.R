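# Synthetic RSVP generator: prevalence, ERP structure, detector streams.

test_that("label prevalence is exact and generation is reproducible", {
  cfg <- erp_sim_config(n_trials = 1500, target_fraction = 0.25,
                        n_channels = 4, sampling_rate = 100, seed = 7)
  ep <- simulate_erp_epochs(cfg)
  expect_equal(sum(ep$labels == 1L), 375L)
  expect_equal(sum(ep$labels == 0L), 1125L)
  ep2 <- simulate_erp_epochs(cfg)
  expect_identical(ep$data, ep2$data)
  expect_identical(ep$labels, ep2$labels)
})

test_that("zero-amplitude components leave no class difference", {
  comps <- lapply(erp_sim_config()$components,
                  function(cp) { cp$peak_amplitude <- 0; cp })
  cfg <- erp_sim_config(n_trials = 200, n_channels = 4,
                        sampling_rate = 100, components = comps, seed = 5)
  ep <- simulate_erp_epochs(cfg)
  diff_wave <- apply(ep$data[ep$labels == 1L, , ], c(2, 3), mean) -
    apply(ep$data[ep$labels == 0L, , ], c(2, 3), mean)
  # Monte-Carlo error of a mean of ~50 vs ~150 noisy trials
  expect_lt(max(abs(diff_wave)), 5)
  expect_lt(mean(abs(diff_wave)), 1.5)
})

test_that("fully lapsed targets are indistinguishable from non-targets", {
  cfg <- erp_sim_config(n_trials = 300, n_channels = 4, sampling_rate = 100,
                        lapse_fraction = 1, seed = 9)
  ep <- simulate_erp_epochs(cfg)
  expect_equal(length(ep$metadata$lapsed), sum(ep$labels == 1L))
  pooled_sd <- stats::sd(ep$data)
  diff_wave <- apply(ep$data[ep$labels == 1L, , ], c(2, 3), mean) -
    apply(ep$data[ep$labels == 0L, , ], c(2, 3), mean)
  expect_lt(max(abs(diff_wave)) / pooled_sd, 0.6)
})

test_that("trial-average target-minus-non-target peaks in the P3 window at Pz", {
  cfg <- erp_sim_config(n_trials = 300, seed = 21)
  ep <- simulate_erp_epochs(cfg)
  pz <- which(ep$channel_names == "Pz")
  dw <- colMeans(ep$data[ep$labels == 1L, pz, ]) -
    colMeans(ep$data[ep$labels == 0L, pz, ])
  t_peak <- ep$time_axis[which.max(dw)]
  expect_gte(t_peak, 0.30)
  expect_lte(t_peak, 0.45)
})

test_that("binormal detector stream matches its closed-form AUC", {
  labels <- rep(c(1L, 0L), c(2500, 7500))
  s0 <- simulate_detector_scores(labels,
                                 detector_sim_config(d_prime = 0, seed = 3))
  expect_lt(abs(auc(s0$posteriors, s0$labels) - 0.5), 0.02)
  s2 <- simulate_detector_scores(labels,
                                 detector_sim_config(d_prime = 2, seed = 3))
  expect_lt(abs(auc(s2$posteriors, s2$labels) - pnorm(2 / sqrt(2))), 0.01)
  # determinism
  s2b <- simulate_detector_scores(labels,
                                  detector_sim_config(d_prime = 2, seed = 3))
  expect_identical(s2$posteriors, s2b$posteriors)
})

test_that("detector AUC is non-decreasing in d-prime on a fixed-seed grid", {
  labels <- rep(c(1L, 0L), c(500, 1500))
  aucs <- vapply(c(0, 0.5, 1, 2, 3), function(d) {
    s <- simulate_detector_scores(labels,
                                  detector_sim_config(d_prime = d, seed = 11))
    auc(s$posteriors, s$labels)
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("dependence parameter induces the requested latent correlation", {
  labels <- rep(c(1L, 0L), c(1000, 3000))
  a <- simulate_detector_scores(labels,
                                detector_sim_config(d_prime = 1, seed = 1))
  b <- simulate_detector_scores(labels,
                                detector_sim_config(d_prime = 1,
                                                    dependence = 0.6,
                                                    seed = 2),
                                partner = a)
  r <- cor(attr(a, "latent_noise"), attr(b, "latent_noise"))
  expect_lt(abs(r - 0.6), 0.05)
})

test_that("configuration invariants are enforced", {
  expect_error(erp_sim_config(target_fraction = 0), class = "dpifuse_config_error")
  expect_error(erp_sim_config(target_fraction = 1), class = "dpifuse_config_error")
  expect_error(erp_sim_config(lapse_fraction = 1.2), class = "dpifuse_config_error")
  expect_error(erp_sim_config(epoch_window = c(0.6, -0.2)),
               class = "dpifuse_config_error")
  expect_error(erp_sim_config(sampling_rate = -1), class = "dpifuse_config_error")
  expect_error(detector_sim_config(d_prime = -1), class = "dpifuse_config_error")
  expect_error(simulate_detector_scores(rep(1L, 10),
                                        detector_sim_config()),
               class = "dpifuse_validation_error")
})
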