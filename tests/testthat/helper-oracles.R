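# Independent oracles used across the suite. These deliberately share no
# code with the implementation they check.

# Brute-force Dempster combination: enumerate all 9 pairs of focal sets on
# {target, non-target, both}, intersect, bin. Masses are length-3 numeric
# (target, nontarget, uncertain).
oracle_dempster <- function(m1, m2) {
  sets <- list(t = "t", n = "n", u = c("t", "n"))
  out <- c(t = 0, n = 0, u = 0)
  conflict <- 0
  for (i in 1:3) for (j in 1:3) {
    inter <- intersect(sets[[i]], sets[[j]])
    w <- m1[i] * m2[j]
    if (length(inter) == 0L) conflict <- conflict + w
    else if (length(inter) == 2L) out["u"] <- out["u"] + w
    else out[inter] <- out[inter] + w
  }
  list(mass = out / (1 - conflict), conflict = conflict)
}

# O(n^2) pairwise AUC, ties counted half.
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# AUC by trapezoidal integration of the empirical ROC.
oracle_auc_trapezoid <- function(scores, labels) {
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(cuts, function(t) mean(scores[labels == 1] >= t), numeric(1))
  fpr <- vapply(cuts, function(t) mean(scores[labels == 0] >= t), numeric(1))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Random valid mass triple.
random_mass <- function() {
  x <- stats::runif(3)
  x / sum(x)
}

# A detection_performance stand-in with constant smoothed curves, for
# exercising the BPA arithmetic at chosen (g, f).
constant_performance <- function(g, f, t_best = 0.5) {
  grid <- seq(0, 1, length.out = 11)
  structure(list(source_id = "fixed", threshold_grid = grid,
                 tpr_raw = rep(g, 11), tnr_raw = rep(f, 11),
                 fpr_raw = rep(1 - f, 11),
                 tpr_smooth = rep(g, 11), tnr_smooth = rep(f, 11),
                 t_best = t_best),
            class = "detection_performance")
}

# Small epoch set with injected class difference, cheap enough for unit
# tests of the decoder chain.
tiny_epochs <- function(n_trials = 60, n_channels = 6, n_samples = 40,
                        effect = 1, seed = 42) {
  withr::with_seed(seed, {
    labels <- rep(c(1L, 0L), length.out = n_trials)
    data <- array(stats::rnorm(n_trials * n_channels * n_samples),
                  dim = c(n_trials, n_channels, n_samples))
    bump <- effect * sin(seq(0, pi, length.out = n_samples))
    for (i in which(labels == 1L)) data[i, 1:2, ] <-
        data[i, 1:2, ] + rep(bump, each = 2)
    epoch_set(data, labels, seq(0, by = 0.01, length.out = n_samples) - 0.1,
              sprintf("ch%d", 1:n_channels), 100)
  })
}

# Score stream of an attention-lapsing binormal source (see
# detector_sim_config(lapse_fraction = )).
lapsing_stream <- function(labels, d_prime, lapse_fraction, seed,
                           source_id = "eeg") {
  simulate_detector_scores(
    labels,
    detector_sim_config(d_prime = d_prime, lapse_fraction = lapse_fraction,
                        seed = seed),
    source_id = source_id)
}

# d' giving a binormal source the requested population AUC.
d_prime_for_auc <- function(auc) sqrt(2) * stats::qnorm(auc)
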