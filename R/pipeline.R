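#' Full analysis configuration
#'
#' Bundles the cohort generator settings with every pipeline constant: the
#' analysis windows, the frequency grid and bands, cross-validation and
#' permutation settings, artifact threshold and seeds.  All downstream
#' stages read their parameters from this object, so a run is fully
#' determined by its config.
#'
#' @param cohort A [cohort_config()].
#' @param fmin,fmax,fstep Frequency grid in Hz (default 4..120, 1 Hz step).
#' @param half_bandwidth Multitaper smoothing half-bandwidth in Hz.
#' @param n_tapers Number of DPSS tapers.
#' @param k_folds Cross-validation folds.
#' @param rejection_threshold Artifact z threshold (see [reject_trials()]).
#' @param n_iterations Permutation iterations for the group null.
#' @param alpha Significance level (per-subject filter and Bonferroni
#'   family level).
#' @param standardize `"per_fold"` or `"global"` (see [svm_crossval()]).
#' @param log_power Log-transform power before decoding (see
#'   [svm_crossval()]).
#' @param fold_seed,permutation_seed Seeds for fold splits and label
#'   permutations (subject `i` uses `fold_seed + i` for its split).
#' @param ranges Named list of frequency restrictions decoded per subject;
#'   each entry is `"full"`, a band name, or a length-2 Hz range.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            fmin = 4, fmax = 120, fstep = 1,
                            half_bandwidth = 4, n_tapers = 9,
                            k_folds = 5, rejection_threshold = 4,
                            n_iterations = 500, alpha = 0.05,
                            standardize = c("per_fold", "global"),
                            log_power = TRUE,
                            fold_seed = 1, permutation_seed = 1,
                            ranges = list(full = "full",
                                          high_gamma = "high_gamma",
                                          theta = "theta",
                                          low_to_beta = c(4, 24),
                                          below_high_gamma = c(4, 59))) {
  validate_cohort_config(cohort)
  win <- analysis_windows()
  if (win$pre[1] < cohort$epoch_window[1] ||
      win$post[2] > cohort$epoch_window[2])
    stop("analysis windows must lie within the epoch window")
  structure(list(cohort = cohort, windows = win,
                 fmin = fmin, fmax = fmax, fstep = fstep,
                 half_bandwidth = half_bandwidth, n_tapers = n_tapers,
                 k_folds = k_folds,
                 rejection_threshold = rejection_threshold,
                 n_iterations = n_iterations, alpha = alpha,
                 standardize = match.arg(standardize),
                 log_power = log_power,
                 fold_seed = fold_seed,
                 permutation_seed = permutation_seed,
                 ranges = ranges),
            class = "pipeline_config")
}

#' Run the full decoding analysis
#'
#' End-to-end pipeline: simulate (or accept) a cohort, epoch, screen and
#' balance each subject's trials, compute pre- and post-stimulus multitaper
#' spectra, decode each subject in every configured frequency range and
#' both windows, and assemble the group-level statistics: the
#' label-permutation null of the group-mean pre-stimulus accuracy, the
#' frequency-band attribution of the classifier weights, the C5/C6
#' stimulation-site lateralization ANOVA on mean high-gamma weights, the
#' pre/post accuracy and FCz high-gamma power correlations, the
#' per-frequency Bonferroni-corrected correlation, and the per-subject
#' trial-series autocorrelation of pre-stimulus high-gamma power at FCz.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-generated `eeg_cohort` (default: generated
#'   from `config$cohort`).
#' @param verbose Emit per-stage progress messages.
#' @return An object of class `group_result`; see [tidy.group_result()] and
#'   [glance.group_result()] for tabular views.
#' @export
run_pipeline <- function(config, cohort = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(cohort)) {
    say("simulating cohort (%d subjects)", config$cohort$n_subjects)
    cohort <- generate_cohort(config$cohort)
  }
  ns <- length(cohort)
  pre_all <- vector("list", ns); post_all <- vector("list", ns)
  pre_bal <- vector("list", ns); post_bal <- vector("list", ns)
  labels <- vector("list", ns)
  decodes <- list()
  acf_tabs <- vector("list", ns)
  sites <- vapply(cohort, `[[`, "", "site")
  for (i in seq_len(ns)) {
    say("subject %d/%d: preprocess + spectra + decode", i, ns)
    rec <- cohort[[i]]
    ts <- epoch_trials(rec, config$cohort$epoch_window)
    am <- artifact_metrics(ts)
    ts <- reject_trials(ts, am, config$rejection_threshold)
    bal <- balance_conditions(ts)
    kept <- attr(bal, "kept")
    pre_all[[i]] <- multitaper_power(
      extract_window(ts, "pre"), config$fmin, config$fmax, config$fstep,
      config$half_bandwidth, config$n_tapers, window_id = "pre")
    post_all[[i]] <- suppressWarnings(multitaper_power(
      extract_window(ts, "post"), config$fmin, config$fmax, config$fstep,
      config$half_bandwidth, config$n_tapers, window_id = "post"))
    pre_bal[[i]] <- features_subset(pre_all[[i]], kept)
    post_bal[[i]] <- features_subset(post_all[[i]], kept)
    labels[[i]] <- as.character(bal$condition)
    for (rg in names(config$ranges)) {
      decodes[[paste("pre", rg, i)]] <- decode_subject(
        pre_bal[[i]], labels[[i]], config$ranges[[rg]], config$k_folds,
        seed = config$fold_seed + i, standardize = config$standardize,
        log_power = config$log_power)
      decodes[[paste("post", rg, i)]] <- decode_subject(
        post_bal[[i]], labels[[i]], config$ranges[[rg]], config$k_folds,
        seed = config$fold_seed + i, standardize = config$standardize,
        log_power = config$log_power)
    }
    series <- band_power_series(pre_all[[i]], "FCz", "high_gamma")
    acf_tab <- trial_autocorrelation(series,
                                     max_lag = min(20, length(series) - 3))
    acf_tab$subject <- i
    acf_tabs[[i]] <- acf_tab
  }
  get_decode <- function(window, rg)
    lapply(seq_len(ns), function(i) decodes[[paste(window, rg, i)]])
  acc_of <- function(res) vapply(res, `[[`, 0, "accuracy")

  pre_full <- get_decode("pre", "full")
  post_full <- get_decode("post", "full")

  say("group permutation null (%d iterations)", config$n_iterations)
  perm <- permutation_null(pre_bal, labels,
                           n_iterations = config$n_iterations,
                           seed = config$permutation_seed,
                           fold_seed = config$fold_seed,
                           k_folds = config$k_folds,
                           standardize = config$standardize,
                           log_power = config$log_power)

  say("band attribution, ANOVA, correlations")
  attribution <- band_argmax_weights(pre_full, p_threshold = config$alpha)

  # small cohorts cannot support every group statistic; degrade with a
  # message rather than aborting the run
  try_stat <- function(expr) tryCatch(expr, error = function(e) {
    message("group statistic skipped: ", conditionMessage(e))
    list(error = conditionMessage(e))
  })

  hg <- frequency_bands()$high_gamma
  mean_hg_weight <- function(res, channel) {
    w <- res$weight_map
    freqs <- as.numeric(colnames(w))
    mean(w[channel, freqs >= hg[1] & freqs <= hg[2]])
  }
  sig <- attribution$per_subject$included
  anova_idx <- which(sig)
  site_tab <- table(factor(sites[anova_idx], levels = c("left", "right")))
  if (any(site_tab < 2)) {
    message("fewer than 2 significant subjects on one site; ",
            "lateralization ANOVA uses all subjects")
    anova_idx <- seq_len(ns)
  }
  anova <- try_stat(lateralization_anova(
    vapply(pre_full[anova_idx], mean_hg_weight, 0, "C5"),
    vapply(pre_full[anova_idx], mean_hg_weight, 0, "C6"),
    sites[anova_idx]))

  acc_cor <- try_stat(accuracy_correlation(acc_of(pre_full),
                                           acc_of(post_full)))
  power_cor <- try_stat(fcz_gamma_correlation(pre_all, post_all))
  freq_cor <- try_stat(per_frequency_correlation(pre_all, post_all,
                                                 alpha = config$alpha))
  acf_table <- do.call(rbind, acf_tabs)

  range_summary <- do.call(rbind, lapply(names(config$ranges), function(rg) {
    do.call(rbind, lapply(c("pre", "post"), function(wd) {
      res <- get_decode(wd, rg)
      tibble::tibble(window = wd, range = rg,
                     subject = seq_len(ns), site = sites,
                     accuracy = acc_of(res),
                     binomial_p = vapply(res, `[[`, 0, "binomial_p"))
    }))
  }))

  site_weight_maps <- lapply(c(left = "left", right = "right"), function(s) {
    maps <- lapply(pre_full[sites == s], `[[`, "weight_map")
    Reduce(`+`, maps) / length(maps)
  })

  structure(list(
    config = config,
    group_accuracy = perm$observed,
    per_site_accuracy = tapply(perm$per_subject, sites, mean),
    null_distribution = perm$null_distribution,
    null_mean = perm$null_mean,
    permutation_p = perm$permutation_p,
    n_significant = sum(sig),
    n_subjects = ns,
    band_attribution = attribution,
    site_mean_weight_maps = site_weight_maps,
    anova = anova,
    accuracy_correlation = acc_cor,
    power_correlation = power_cor,
    per_frequency = freq_cor,
    autocorrelation = acf_table,
    decoding_summary = range_summary,
    subject_results = list(pre_full = pre_full, post_full = post_full)
  ), class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat("<group_result>\n")
  cat(sprintf("  group accuracy %.3f (null mean %.3f), permutation p = %.4g\n",
              x$group_accuracy, x$null_mean, x$permutation_p))
  cat(sprintf("  %d / %d subjects individually significant\n",
              x$n_significant, x$n_subjects))
  cat("  band attribution:",
      paste(names(x$band_attribution$counts), x$band_attribution$counts,
            sep = "=", collapse = ", "), "\n")
  if (!is.null(x$anova$F))
    cat(sprintf("  site x electrode interaction F(%d, %d) = %.2f, p = %.4g\n",
                x$anova$df1, x$anova$df2, x$anova$F, x$anova$p))
  if (!is.null(x$accuracy_correlation$r) && !is.null(x$power_correlation$r))
    cat(sprintf("  pre/post accuracy r = %.2f; FCz high-gamma power r = %.2f\n",
                x$accuracy_correlation$r, x$power_correlation$r))
  invisible(x)
}
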