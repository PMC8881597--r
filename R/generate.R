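#' Generate one synthetic subject recording
#'
#' Simulates a continuous multichannel EEG recording for one subject of a
#' near-threshold pain experiment.  The signal is the sum of
#'
#' * a 1/f^`background_exponent` Gaussian background (per-channel
#'   independent, RMS 10 uV), emulating ongoing broadband EEG;
#' * per-trial pre-stimulus gamma bursts: amplitude-modulated bandpass
#'   noise in a subject-specific 10 Hz-wide band inside 65-95 Hz, under a
#'   Hann envelope spanning -1.5 to -0.25 s before each stimulus, whose
#'   per-channel log-amplitude follows a latent per-trial state;
#' * a post-stimulus evoked gamma component (0.05-1 s) whose subject-level
#'   amplitude is coupled to the subject-level pre-stimulus amplitude at
#'   correlation `pre_post_coupling_rho` across subjects.
#'
#' The latent per-trial state `g_t` is a stationary AR(1) sequence with unit
#' marginal variance and lag-1 autocorrelation `trial_ar1_phi`.  The trial's
#' class (pain / no pain) is drawn from `g_t` through a probit link whose
#' strength is calibrated so the standardized class difference of the state
#' at the fronto-central focus channels equals `effect_size_d`; the central
#' channel contralateral to the stimulated hand carries an extra
#' `+lateralization_delta`, the ipsilateral channel `-lateralization_delta`.
#' Ratings are then drawn from class-conditional truncated normals (no-pain
#' in \[0, 50), pain in (50, 100\]; 50 itself is never emitted), so the
#' rating, the report and the gamma state are mutually dependent — the
#' pre-stimulus state genuinely predicts the report.
#'
#' The latent states are stored in `$ground_truth` for recovery tests only;
#' no pipeline stage reads them.
#'
#' @param config A [cohort_config()].
#' @param subject_index 1-based subject index (determines site and seed).
#' @param signal Synthesize the continuous waveform (default `TRUE`).  With
#'   `FALSE` only events, latent states and ratings are drawn -- bit
#'   identical to the corresponding draws of a full generation -- which
#'   makes large-sample calibration checks of the latent model cheap.
#' @return An object of class `subject_recording`: a list with `signal`
#'   (channels x samples matrix, uV, rownames = montage), `sampling_rate`,
#'   `event_samples` (1-based stimulus-onset indices), `ratings`, `site`,
#'   `montage`, `subject_index` and `ground_truth`.
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 1, n_trials_per_condition = 8,
#'                      montage = montage_16(), seed = 7)
#' rec <- generate_subject(cfg, 1)
#' dim(rec$signal)
generate_subject <- function(config, subject_index, signal = TRUE) {
  validate_cohort_config(config)
  if (subject_index < 1 || subject_index > config$n_subjects)
    stop("subject_index must be in 1..n_subjects")
  rate <- config$sampling_rate
  epoch_len <- diff(config$epoch_window)
  burst_support <- c(-1.5, -0.25)
  evoked_support <- c(0.05, 1.0)
  if (config$epoch_window[1] > burst_support[1] ||
      config$epoch_window[2] < evoked_support[2])
    stop("epoch_window is shorter than the burst support")

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(subject_seed(config$seed, subject_index))

  site <- config$site_assignment[subject_index]
  n_trials <- 2L * config$n_trials_per_condition
  n_chan <- length(config$montage)

  # event grid: lead-in/out of 2.5 s, inter-stimulus interval 5-6 s
  gaps <- runif(n_trials - 1, 5, 6)
  onset_times <- 2.5 + c(0, cumsum(gaps))
  event_samples <- 1L + as.integer(round(onset_times * rate))
  n_samples <- max(event_samples) + as.integer(ceiling(2.5 * rate))

  # latent AR(1) state, unit marginal variance
  phi <- config$trial_ar1_phi
  g <- numeric(n_trials)
  g[1] <- rnorm(1)
  if (n_trials > 1)
    for (t in 2:n_trials)
      g[t] <- phi * g[t - 1] + sqrt(1 - phi^2) * rnorm(1)

  # probit link calibrated so the standardized class difference of g is d
  d <- config$effect_size_d
  lambda <- probit_link_strength(d)
  is_pain <- (lambda * g + sqrt(1 - lambda^2) * rnorm(n_trials)) > 0
  s_within <- sqrt(1 - lambda^2 * 2 / pi)   # within-class SD of g

  # post-stimulus latent state: same class-conditional moments as g but an
  # independent residual, so the across-subject pre/post power coupling is
  # governed by pre_post_coupling_rho alone and not additionally inflated
  # by shared trial-mean fluctuations
  m_class <- ifelse(is_pain, 1, -1) * lambda * sqrt(2 / pi)
  g_post <- m_class + s_within * rnorm(n_trials)

  # Burst topography: every channel expresses the shared gamma state g_t;
  # the per-channel class effect d_c shifts the state mean by class (focus
  # channels d, contralateral central +delta, ipsilateral -delta, others 0)
  contra <- if (site == "left") "C6" else "C5"
  ipsi <- if (site == "left") "C5" else "C6"
  focus <- intersect(focus_channels(), config$montage)
  d_chan <- setNames(numeric(n_chan), config$montage)
  d_chan[focus] <- d
  d_chan[contra] <- config$lateralization_delta
  d_chan[ipsi] <- -config$lateralization_delta

  # Subject-level pre/post amplitude factors.  Subject-mean band power
  # scales as the lognormal exp(v), v ~ N(0, 0.5), times the trial-mean of
  # exp(2*kappa*h) whose log-variance is about (e^{4 kappa^2} - 1)/T for T
  # trials.  The correlation of the underlying normals is calibrated so the
  # POWER-scale across-subject correlation, including that trial-mean
  # noise, equals pre_post_coupling_rho.
  rho <- config$pre_post_coupling_rho
  sigma2_v <- 0.5
  nu_trial <- (exp(1) - 1) / (2 * config$n_trials_per_condition)
  w2 <- sigma2_v + nu_trial
  if (1 + rho * (exp(w2) - 1) <= 0)
    stop("pre_post_coupling_rho too negative for the lognormal power model")
  rho_z <- min(1, log(1 + rho * (exp(w2) - 1)) / sigma2_v)
  u_pre <- rnorm(1, sd = sqrt(sigma2_v))
  u_post <- rho_z * u_pre + sqrt(sigma2_v - rho_z^2 * sigma2_v) * rnorm(1)
  subj_pre <- exp(0.5 * u_pre)
  subj_post <- exp(0.5 * u_post)

  # subject-specific gamma peaks: individuals express induced gamma as
  # narrow components at individual frequencies; two 4 Hz-wide carriers
  # centered in 68-78 and 82-95 Hz keep the bursts, their +/-4 Hz
  # multitaper smoothing and the leakage skirts inside the 60-120 Hz band
  band_lo <- runif(1, 68, 78) + c(-2, 2)
  band_hi <- runif(1, 82, 95) + c(-2, 2)

  ratings <- draw_ratings(is_pain, config$rating_params)

  sig <- NULL
  if (signal) {
  # background
  sig <- matrix(0, n_chan, n_samples,
                dimnames = list(config$montage, NULL))
  for (c in seq_len(n_chan))
    sig[c, ] <- 10 * colored_noise(n_samples, config$background_exponent, rate)

  # gamma bursts: independent carrier noise per channel, trial and window,
  # with per-channel amplitude exp(kappa * state) so channels are linked
  # only through the latent state
  kappa <- 0.5
  pre_idx <- burst_index(burst_support, rate)
  post_idx <- burst_index(evoked_support, rate)
  amp_pre0 <- 6 * subj_pre       # uV RMS at state 0
  amp_post0 <- 8 * subj_post
  cls <- ifelse(is_pain, 0.5, -0.5)
  # each burst is a narrow subject-specific peak riding on a broadband
  # 66-108 Hz pedestal, both amplitude-modulated by the same latent state:
  # induced gamma is broadband with an individually peaked component, and
  # the pedestal spreads the class effect over the whole high-gamma band
  for (t in seq_len(n_trials)) {
    h_pre <- g[t] + s_within * (d_chan - d) * cls[t]
    h_post <- g_post[t] + s_within * (d_chan - d) * cls[t]
    carrier_pre <- (gamma_burst_bank(n_chan, length(pre_idx), rate, band_lo) +
                    gamma_burst_bank(n_chan, length(pre_idx), rate, band_hi)) / sqrt(2)
    carrier_post <- (gamma_burst_bank(n_chan, length(post_idx), rate, band_lo) +
                     gamma_burst_bank(n_chan, length(post_idx), rate, band_hi)) / sqrt(2)
    cols_pre <- event_samples[t] + pre_idx
    cols_post <- event_samples[t] + post_idx
    sig[, cols_pre] <- sig[, cols_pre] +
      (amp_pre0 * exp(kappa * h_pre)) * carrier_pre
    sig[, cols_post] <- sig[, cols_post] +
      (amp_post0 * exp(kappa * h_post)) * carrier_post
  }
  }

  structure(list(
    signal = sig,
    sampling_rate = rate,
    event_samples = event_samples,
    ratings = ratings,
    site = site,
    montage = config$montage,
    subject_index = as.integer(subject_index),
    ground_truth = list(g = g, g_post = g_post, is_pain = is_pain,
                        channel_effect = d_chan,
                        u_pre = u_pre, u_post = u_post,
                        link_lambda = lambda)
  ), class = "subject_recording")
}

#' Generate a synthetic cohort
#'
#' Calls [generate_subject()] for every subject in the configuration.  Each
#' subject is seeded deterministically from `(config$seed, subject_index)`,
#' so the cohort is reproducible and individual subjects can be regenerated
#' in isolation.
#'
#' @param config A [cohort_config()].
#' @return An object of class `eeg_cohort`: a list of
#'   `subject_recording`s with the config attached as attribute `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) generate_subject(config, i))
  structure(subjects, class = "eeg_cohort", config = config)
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("<subject_recording> subject %d (%s hand): %d channels, %d events, %.1f s @ %g Hz\n",
              x$subject_index, x$site, nrow(x$signal),
              length(x$event_samples),
              ncol(x$signal) / x$sampling_rate, x$sampling_rate))
  invisible(x)
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<eeg_cohort> %d subjects (%d left / %d right)\n",
              length(x), sum(cfg$site_assignment == "left"),
              sum(cfg$site_assignment == "right")))
  invisible(x)
}

# --- internals --------------------------------------------------------------

# link strength lambda such that with pain := (lambda*g + sqrt(1-lambda^2)*e > 0),
# the standardized class difference of g equals d
probit_link_strength <- function(d) {
  if (d == 0) return(0)
  a <- d^2 / (4 + d^2)            # = lambda^2 * 2/pi
  lambda2 <- a * pi / 2
  if (lambda2 >= 1)
    stop("effect_size_d too large for the probit link (must be < ",
         round(sqrt(4 * (2 / pi) / (1 - 2 / pi)), 2), ")")
  sign(d) * sqrt(lambda2)
}

# Gaussian noise with power spectrum ~ 1/f^exponent, unit RMS.
# Frequencies below 1 Hz are flattened (recordings are high-pass filtered).
colored_noise <- function(n, exponent, rate) {
  m <- stats::nextn(n, c(2, 3, 5))   # smooth length keeps the FFT fast
  white <- rnorm(m)
  spec <- fft(white)
  f <- seq(0, rate, length.out = m + 1)[seq_len(m)]
  f[f > rate / 2] <- rate - f[f > rate / 2]   # fold to physical frequency
  f <- pmax(f, 1)
  shaped <- spec * f^(-exponent / 2)
  x <- Re(fft(shaped, inverse = TRUE))[seq_len(n)] / m
  x / sd(x)
}

# sample offsets of a burst support window relative to the event sample
burst_index <- function(support, rate) {
  seq.int(as.integer(round(support[1] * rate)),
          as.integer(round(support[2] * rate)) - 1L)
}

# Hann-enveloped bandpass noise, unit RMS over its support.  Broadband
# carrier (not a sinusoid) so multitaper smoothing behaves as it would on
# induced gamma.
gamma_burst <- function(m, rate, band) {
  drop(gamma_burst_bank(1L, m, rate, band))
}

# n_chan independent burst realizations as rows of an n_chan x m matrix
gamma_burst_bank <- function(n_chan, m, rate, band) {
  white <- matrix(rnorm(n_chan * m), m, n_chan)
  spec <- mvfft(white)
  f <- seq(0, rate, length.out = m + 1)[seq_len(m)]
  f[f > rate / 2] <- rate - f[f > rate / 2]
  spec[f < band[1] | f > band[2], ] <- 0
  x <- Re(mvfft(spec, inverse = TRUE)) / m
  env <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = m))
  x <- x * env
  t(x) / sqrt(colMeans(x^2))
}

# class-conditional truncated normal ratings; 50 is never emitted
draw_ratings <- function(is_pain, rp) {
  n <- length(is_pain)
  mu <- ifelse(is_pain, rp$pain_mean, rp$nopain_mean)
  sigma <- ifelse(is_pain, rp$pain_sd, rp$nopain_sd)
  out <- rnorm(n, mu, sigma)
  for (iter in 1:10000) {
    # no-pain ratings live in [0, 50), pain in (50, 100]; 50 never emitted
    bad <- ifelse(is_pain, out <= 50 | out > 100, out < 0 | out >= 50)
    if (!any(bad)) return(out)
    out[bad] <- rnorm(sum(bad), mu[bad], sigma[bad])
  }
  stop("rating truncation bounds could not be satisfied; check rating_params")
}

# save/restore .Random.seed so generation does not disturb the caller's RNG
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
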