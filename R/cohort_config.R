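#' Configuration for a synthetic EEG cohort
#'
#' Bundles every parameter of the synthetic cohort generator.  The defaults
#' describe a near-threshold electrical pain experiment: 60-channel extended
#' 10-20 montage sampled at 250 Hz, roughly 40 trials per condition per
#' subject, visual-analog-scale (VAS) ratings with the pain threshold fixed
#' at 50 (which can never be emitted), and a pre-stimulus high-gamma state
#' that genuinely predicts the report.
#'
#' @param n_subjects Number of subjects in the cohort.
#' @param n_trials_per_condition Target number of trials per condition; the
#'   generator emits `2 * n_trials_per_condition` stimulation events whose
#'   class labels arise stochastically from the latent gamma state, so the
#'   realized counts fluctuate around this target.  Must be at least 5 so a
#'   five-fold split keeps both classes in every fold.
#' @param sampling_rate Sampling rate in Hz.
#' @param montage Character vector of unique channel labels; must contain
#'   FCz, Cz, C5 and C6.
#' @param epoch_window Length-2 numeric, epoch limits in seconds relative to
#'   stimulus onset.
#' @param site_assignment Character vector (`"left"`/`"right"`) of length
#'   `n_subjects` giving each subject's stimulated hand.  The default splits
#'   the cohort 20:13 left:right, scaled to `n_subjects`.
#' @param effect_size_d Standardized pain/no-pain difference of the latent
#'   pre-stimulus gamma state at the fronto-central focus channels.
#' @param lateralization_delta Signed asymmetry of the latent effect between
#'   the central channel contralateral to the stimulated hand (C6 for left
#'   stimulation, C5 for right) and the ipsilateral one; the contralateral
#'   channel carries `+lateralization_delta`, the ipsilateral
#'   `-lateralization_delta`.  Default `0.4 * effect_size_d`.
#' @param pre_post_coupling_rho Across-subject correlation between the
#'   subject-level pre-stimulus gamma-burst amplitude and the post-stimulus
#'   evoked gamma amplitude.
#' @param trial_ar1_phi Lag-1 autocorrelation of the latent per-trial gamma
#'   state across the trial sequence (AR(1) coefficient).
#' @param rating_params Named list with `nopain_mean`, `nopain_sd`,
#'   `pain_mean`, `pain_sd`: parameters of the class-conditional truncated
#'   normal rating distributions (no-pain truncated to \[0, 50), pain to
#'   (50, 100\]).
#' @param background_exponent Spectral exponent of the 1/f background.
#' @param seed Integer seed; together with the subject index it fully
#'   determines each recording.
#'
#' @return An object of class `cohort_config` (a named list).
#' @export
#' @examples
#' cfg <- cohort_config(n_subjects = 2, n_trials_per_condition = 10,
#'                      montage = montage_16())
#' cfg$effect_size_d
cohort_config <- function(n_subjects = 33,
                          n_trials_per_condition = 40,
                          sampling_rate = 250,
                          montage = montage_60(),
                          epoch_window = c(-2, 2),
                          site_assignment = NULL,
                          effect_size_d = 0.8,
                          lateralization_delta = 0.4 * effect_size_d,
                          pre_post_coupling_rho = 0.85,
                          trial_ar1_phi = 0,
                          rating_params = list(nopain_mean = 40, nopain_sd = 12,
                                               pain_mean = 55.2, pain_sd = 6.4),
                          background_exponent = 1,
                          seed = 1L) {
  if (is.null(site_assignment)) {
    n_left <- round(n_subjects * 20 / 33)
    site_assignment <- rep(c("left", "right"), c(n_left, n_subjects - n_left))
  }
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects),
    n_trials_per_condition = as.integer(n_trials_per_condition),
    sampling_rate = sampling_rate,
    montage = as.character(montage),
    epoch_window = as.numeric(epoch_window),
    site_assignment = as.character(site_assignment),
    effect_size_d = effect_size_d,
    lateralization_delta = lateralization_delta,
    pre_post_coupling_rho = pre_post_coupling_rho,
    trial_ar1_phi = trial_ar1_phi,
    rating_params = rating_params,
    background_exponent = background_exponent,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1")
  if (cfg$n_trials_per_condition < 5)
    stop("n_trials_per_condition must be >= 5 (five-fold cross-validation ",
         "needs both classes in every fold)")
  if (cfg$sampling_rate <= 0) stop("sampling_rate must be positive")
  if (anyDuplicated(cfg$montage))
    stop("montage labels must be unique")
  missing_ch <- setdiff(required_channels(), cfg$montage)
  if (length(missing_ch))
    stop("montage must contain required channels: ",
         paste(missing_ch, collapse = ", "))
  if (length(cfg$epoch_window) != 2 || diff(cfg$epoch_window) <= 0)
    stop("epoch_window must be an increasing pair of seconds")
  if (length(cfg$site_assignment) != cfg$n_subjects)
    stop("site_assignment must have one entry per subject")
  if (!all(cfg$site_assignment %in% c("left", "right")))
    stop("site_assignment entries must be 'left' or 'right'")
  if (abs(cfg$trial_ar1_phi) >= 1)
    stop("trial_ar1_phi must lie in (-1, 1)")
  if (abs(cfg$pre_post_coupling_rho) > 1)
    stop("pre_post_coupling_rho must lie in [-1, 1]")
  rp <- cfg$rating_params
  need <- c("nopain_mean", "nopain_sd", "pain_mean", "pain_sd")
  if (!all(need %in% names(rp)))
    stop("rating_params must name: ", paste(need, collapse = ", "))
  if (rp$nopain_mean >= 50 || rp$nopain_mean < 0)
    stop("nopain_mean must lie in [0, 50)")
  if (rp$pain_mean <= 50 || rp$pain_mean > 100)
    stop("pain_mean must lie in (50, 100]")
  if (rp$nopain_sd <= 0 || rp$pain_sd <= 0)
    stop("rating SDs must be positive")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects (%d left / %d right), ~%d trials/condition\n",
              x$n_subjects, sum(x$site_assignment == "left"),
              sum(x$site_assignment == "right"), x$n_trials_per_condition))
  cat(sprintf("  %d channels @ %g Hz, epoch [%g, %g] s\n",
              length(x$montage), x$sampling_rate,
              x$epoch_window[1], x$epoch_window[2]))
  cat(sprintf("  effect d = %g, lateralization = %g, coupling rho = %g, AR1 phi = %g\n",
              x$effect_size_d, x$lateralization_delta,
              x$pre_post_coupling_rho, x$trial_ar1_phi))
  invisible(x)
}

# deterministic per-subject seed below 2^31
subject_seed <- function(seed, subject_index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * subject_index) %% 2147483629)
}
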