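# Synthetic RSVP data: EEG epochs with controllable ERP structure and paired
# detector score streams, so the whole decode/fuse/evaluate chain is testable
# without real recordings.

#' Standard 64-channel montage used by the simulator
#'
#' Extended 10-20 (10-10) channel names, central-parietal reference
#' convention. Used to give the simulated ERP components spatially
#' meaningful scalp profiles (occipital P1, broad N2, central-parietal P3).
#'
#' @return character vector of 64 channel names.
#' @export
montage_64 <- function() {
  c("Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
    "O1", "Oz", "O2", "Iz")
}

# Fixed scalp weight profiles over the montage; values in [0, 1].
scalp_profile <- function(channel_names, which = c("lateral_occipital",
                                                   "broad",
                                                   "central_parietal")) {
  which <- match.arg(which)
  w <- rep(0.05, length(channel_names))
  names(w) <- channel_names
  hit <- function(chs, val) {
    idx <- channel_names %in% chs
    w[idx] <<- pmax(w[idx], val)
  }
  switch(which,
    lateral_occipital = {
      hit(c("PO7", "PO8", "O1", "O2"), 1)
      hit(c("PO5", "PO6", "P7", "P8", "Oz", "Iz"), 0.6)
      hit(c("PO3", "PO4", "P5", "P6"), 0.3)
    },
    broad = {
      w[] <- 0.5
      hit(c("Fz", "FCz", "Cz", "FC1", "FC2", "C1", "C2", "F1", "F2"), 0.8)
    },
    central_parietal = {
      hit(c("Pz", "CPz", "P1", "P2", "CP1", "CP2"), 1)
      hit(c("Cz", "C1", "C2", "P3", "P4", "CP3", "CP4", "POz"), 0.7)
      hit(c("FCz", "P5", "P6", "PO3", "PO4"), 0.3)
    })
  w
}

default_components <- function() {
  list(
    list(name = "P1", window_ms = c(100, 150), polarity = +1,
         peak_amplitude = 3, profile = "lateral_occipital"),
    list(name = "N2", window_ms = c(150, 250), polarity = -1,
         peak_amplitude = 4, profile = "broad"),
    list(name = "P3", window_ms = c(350, 400), polarity = +1,
         peak_amplitude = 6, profile = "central_parietal")
  )
}

#' Configuration for the synthetic RSVP EEG generator
#'
#' Defaults emulate the simulated study conditions: 1,500 trials at 25%
#' target prevalence, 64 channels at 250 Hz, epochs from -200 to +600 ms
#' around stimulus onset, and target-trial ERP components P1 (100-150 ms,
#' positive, lateral-occipital), N2 (150-250 ms, negative, broad) and P3
#' (350-400 ms, positive, central-parietal) added over 1/f + 10 Hz
#' oscillatory + white background noise. A `lapse_fraction` of the target
#' trials carries no ERP at all (simulated attention lapses).
#'
#' @param n_trials number of trials.
#' @param target_fraction proportion of target trials, in (0, 1).
#' @param n_channels number of channels (<= 64; names taken from
#'   [montage_64()]).
#' @param sampling_rate sampling rate in Hz.
#' @param epoch_window `c(start, end)` in seconds relative to stimulus onset.
#' @param components list of component specs
#'   (`name`, `window_ms`, `polarity`, `peak_amplitude` in microvolts,
#'   `profile` name understood by the montage profiles).
#' @param noise list with elements `pink_sd`, `pink_exponent`,
#'   `oscillation_freq`, `oscillation_amp`, `white_sd` (microvolts / Hz).
#' @param lapse_fraction fraction of target trials carrying no ERP, in
#'   \[0, 1\].
#' @param amplitude_jitter_sd per-trial multiplicative amplitude jitter sd.
#' @param latency_jitter_ms per-trial latency jitter sd (ms).
#' @param seed integer seed; fans out into independent sub-streams for trial
#'   order, noise, lapse selection and jitter.
#'
#' @return an object of class `erp_sim_config`.
#' @export
erp_sim_config <- function(n_trials = 1500, target_fraction = 0.25,
                           n_channels = 64, sampling_rate = 250,
                           epoch_window = c(-0.2, 0.6),
                           components = default_components(),
                           noise = list(pink_sd = 9, pink_exponent = 1,
                                        oscillation_freq = 10,
                                        oscillation_amp = 3, white_sd = 2),
                           lapse_fraction = 0,
                           amplitude_jitter_sd = 0.25,
                           latency_jitter_ms = 15,
                           seed = 1L) {
  if (!is_count(n_trials) || n_trials < 2)
    stop_dpifuse("n_trials must be an integer >= 2", "dpifuse_config_error")
  if (!is_number(target_fraction) || target_fraction <= 0 || target_fraction >= 1)
    stop_dpifuse("target_fraction must lie strictly in (0, 1)",
                 "dpifuse_config_error")
  if (!is_number(lapse_fraction) || lapse_fraction < 0 || lapse_fraction > 1)
    stop_dpifuse("lapse_fraction must lie in [0, 1]", "dpifuse_config_error")
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    stop_dpifuse("sampling_rate must be positive", "dpifuse_config_error")
  if (epoch_window[1L] >= epoch_window[2L])
    stop_dpifuse("epoch window start must precede end", "dpifuse_config_error")
  if (!is_count(n_channels) || n_channels > length(montage_64()))
    stop_dpifuse("n_channels must be a count <= 64", "dpifuse_config_error")
  structure(
    list(n_trials = as.integer(n_trials), target_fraction = target_fraction,
         n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
         epoch_window = epoch_window, components = components, noise = noise,
         lapse_fraction = lapse_fraction,
         amplitude_jitter_sd = amplitude_jitter_sd,
         latency_jitter_ms = latency_jitter_ms, seed = as.integer(seed)),
    class = "erp_sim_config"
  )
}

# Unit-variance 1/f^alpha noise, one column per channel, via spectral shaping.
pink_noise <- function(n_samples, n_channels, exponent, fs) {
  freqs <- c(0, seq_len(n_samples - 1)) * fs / n_samples
  freqs <- pmin(freqs, fs - freqs)          # fold to |f| on the fft grid
  scale <- c(0, 1 / freqs[-1L]^(exponent / 2))
  scale <- scale / sqrt(mean(scale^2))      # unit expected output variance
  white <- matrix(stats::rnorm(n_samples * n_channels), n_samples, n_channels)
  shaped <- stats::mvfft(white) * scale
  Re(stats::mvfft(shaped, inverse = TRUE)) / n_samples
}

#' Generate synthetic RSVP EEG epochs
#'
#' Exactly `round(n_trials * target_fraction)` trials are labelled target and
#' receive the additive ERP components with per-trial amplitude and latency
#' jitter — except a randomly chosen `lapse_fraction` subset, which (like all
#' non-target trials) contains background noise only. Reproducible given the
#' config seed.
#'
#' @param config an [erp_sim_config()].
#' @return an [epoch_set()]; `metadata$lapsed` flags the lapsed target trials.
#' @export
simulate_erp_epochs <- function(config) {
  stopifnot(inherits(config, "erp_sim_config"))
  fs <- config$sampling_rate
  n_samp <- round((config$epoch_window[2L] - config$epoch_window[1L]) * fs)
  time_axis <- config$epoch_window[1L] + (seq_len(n_samp) - 1L) / fs
  n <- config$n_trials
  n_target <- round(n * config$target_fraction)
  if (n_target < 1L || n_target > n - 1L)
    stop_dpifuse("target_fraction leaves a class empty", "dpifuse_config_error")
  channels <- montage_64()[seq_len(config$n_channels)]

  labels <- integer(n)
  labels[with_seed(sub_seed(config$seed, "order"),
                   sample.int(n, n_target))] <- 1L

  target_idx <- which(labels == 1L)
  n_lapse <- round(config$lapse_fraction * n_target)
  lapsed <- with_seed(sub_seed(config$seed, "lapse"),
                      sample(target_idx, n_lapse))
  erp_idx <- setdiff(target_idx, lapsed)

  profiles <- lapply(config$components, function(cp)
    scalp_profile(channels, cp$profile))

  nz <- config$noise
  nch <- config$n_channels
  data <- with_seed(sub_seed(config$seed, "noise"), {
    arr <- array(0, dim = c(n, nch, n_samp))
    chunk <- 128L                               # trials per FFT batch
    for (lo in seq(1L, n, by = chunk)) {
      hi <- min(lo + chunk - 1L, n)
      nb <- hi - lo + 1L
      x <- nz$pink_sd * pink_noise(n_samp, nch * nb, nz$pink_exponent, fs)
      phase <- stats::runif(nch * nb, 0, 2 * pi)
      x <- x + nz$oscillation_amp *
        sin(outer(2 * pi * nz$oscillation_freq *
                    (time_axis - time_axis[1L]), phase, `+`)) +
        nz$white_sd * stats::rnorm(n_samp * nch * nb)
      # columns are channel-fastest within each trial of the batch
      arr[lo:hi, , ] <- aperm(array(x, dim = c(n_samp, nch, nb)),
                              c(3L, 2L, 1L))
    }
    arr
  })

  data <- with_seed(sub_seed(config$seed, "jitter"), {
    for (i in erp_idx) {
      for (k in seq_along(config$components)) {
        cp <- config$components[[k]]
        amp <- cp$peak_amplitude *
          max(0, 1 + stats::rnorm(1, 0, config$amplitude_jitter_sd))
        centre <- mean(cp$window_ms) / 1000 +
          stats::rnorm(1, 0, config$latency_jitter_ms) / 1000
        width <- diff(cp$window_ms) / 1000
        bump <- amp * cp$polarity *
          exp(-0.5 * ((time_axis - centre) / (width / 4))^2)
        data[i, , ] <- data[i, , ] + outer(profiles[[k]], bump)
      }
    }
    data
  })

  epoch_set(data, labels, time_axis, channels, fs,
            metadata = list(lapsed = as.integer(lapsed),
                            generator = "simulate_erp_epochs",
                            seed = config$seed))
}

#' Configuration for a synthetic heterogeneous detector
#'
#' A binormal score model standing in for an external detector's posterior
#' stream: latent score = `d_prime * label + noise`, mapped through a
#' monotone logistic link to a posterior in (0, 1). The population AUC of
#' such a detector is `pnorm(d_prime / sqrt(2))`.
#'
#' @param d_prime binormal discriminability, >= 0.
#' @param noise_sd latent noise standard deviation (> 0).
#' @param dependence correlation in \[-1, 1\] between this source's latent
#'   noise and a partner stream's latent noise (see
#'   [simulate_detector_scores()]).
#' @param link monotone map from latent score to posterior; default
#'   `plogis` centred at `d_prime / 2`.
#' @param lapse_fraction fraction of target trials on which the source is
#'   blind (latent signal 0, as for a non-target) — the score-stream
#'   analogue of an attention lapse.
#' @param seed integer seed.
#' @return an object of class `detector_sim_config`.
#' @export
detector_sim_config <- function(d_prime = 1.5, noise_sd = 1, dependence = 0,
                                link = NULL, lapse_fraction = 0, seed = 1L) {
  if (!is_number(d_prime) || d_prime < 0)
    stop_dpifuse("d_prime must be >= 0", "dpifuse_config_error")
  if (!is_number(noise_sd) || noise_sd <= 0)
    stop_dpifuse("noise_sd must be positive", "dpifuse_config_error")
  if (!is_number(dependence) || abs(dependence) > 1)
    stop_dpifuse("dependence must lie in [-1, 1]", "dpifuse_config_error")
  if (!is_number(lapse_fraction) || lapse_fraction < 0 || lapse_fraction > 1)
    stop_dpifuse("lapse_fraction must lie in [0, 1]", "dpifuse_config_error")
  structure(
    list(d_prime = d_prime, noise_sd = noise_sd, dependence = dependence,
         link = link, lapse_fraction = lapse_fraction,
         seed = as.integer(seed)),
    class = "detector_sim_config"
  )
}

#' Generate synthetic detector posteriors for a set of labelled trials
#'
#' @param labels binary 0/1 vector (both classes must be present).
#' @param config a [detector_sim_config()].
#' @param partner optionally, a `score_set` previously returned by this
#'   function; `config$dependence` then sets the correlation between the two
#'   streams' latent noises (conditional on the label).
#' @param source_id name for the returned stream.
#' @return a [score_set()]; the latent noise is attached as attribute
#'   `"latent_noise"` so a correlated partner stream can be generated.
#' @export
simulate_detector_scores <- function(labels, config, partner = NULL,
                                     source_id = "detector") {
  stopifnot(inherits(config, "detector_sim_config"))
  labels <- as.integer(labels)
  if (length(labels) == 0L)
    stop_dpifuse("labels must be non-empty", "dpifuse_validation_error")
  check_two_classes(labels, "label vector")
  n <- length(labels)
  noise <- with_seed(sub_seed(config$seed, "detector_noise"), stats::rnorm(n))
  if (!is.null(partner)) {
    pn <- attr(partner, "latent_noise")
    if (is.null(pn) || length(pn) != n)
      stop_dpifuse("partner stream carries no compatible latent noise",
                   "dpifuse_validation_error")
    rho <- config$dependence
    noise <- rho * pn + sqrt(1 - rho^2) * noise
  }
  signal_on <- as.numeric(labels)
  if (config$lapse_fraction > 0) {
    tgt <- which(labels == 1L)
    lapsed <- with_seed(sub_seed(config$seed, "detector_lapse"),
                        sample(tgt, round(config$lapse_fraction *
                                            length(tgt))))
    signal_on[lapsed] <- 0
  }
  latent <- config$d_prime * signal_on + config$noise_sd * noise
  link <- config$link
  if (is.null(link))
    link <- function(x) stats::plogis(x - config$d_prime / 2)
  post <- pmin(1, pmax(0, link(latent)))
  out <- score_set(post, labels, source_id = source_id)
  attr(out, "latent_noise") <- noise
  out
}
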