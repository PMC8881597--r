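#' Group-level permutation test of decoding accuracy
#'
#' Builds the null distribution of the group-mean decoding accuracy by
#' repeatedly permuting the condition labels within each subject and
#' re-running the per-subject cross-validated SVM with identical settings.
#' The fold geometry is held fixed at the observed (stratified) split and
#' labels are permuted within each fold.  Within-fold permutations are a
#' subgroup of the full within-subject permutation group, so the null is
#' exact under label exchangeability, and they preserve the class balance of
#' every training and test fold -- avoiding the spurious below-chance bias
#' that cross-validated accuracy shows when free label permutation
#' unbalances the folds.  The p-value uses the add-one rule
#' `(1 + #[null >= observed]) / (1 + n_iterations)` and can therefore never
#' be exactly zero.
#'
#' @param features_list List of per-subject [spectral_features()] (one
#'   window, one frequency range).
#' @param labels_list List of per-subject balanced label vectors.
#' @param n_iterations Number of permutation iterations (>= 1).
#' @param seed Seed for the label permutations.
#' @param fold_seed Base seed for the per-subject fold splits (subject `i`
#'   uses `fold_seed + i`).
#' @param k_folds Folds per subject.
#' @param standardize,log_power Passed to [svm_crossval()].
#' @return List with `observed` (group mean accuracy), `per_subject`
#'   (observed per-subject accuracies), `null_distribution` (length
#'   `n_iterations`), `null_mean` and `permutation_p`.
#' @export
permutation_null <- function(features_list, labels_list, n_iterations = 500,
                             seed = 1, fold_seed = 1, k_folds = 5,
                             standardize = "per_fold", log_power = TRUE) {
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  ns <- length(features_list)
  stopifnot(ns == length(labels_list))
  preps <- vector("list", ns)
  obs <- numeric(ns)
  for (i in seq_len(ns)) {
    labels <- as.character(labels_list[[i]])
    tab <- table(labels)
    if (length(tab) != 2 || tab[1] != tab[2])
      stop("subject ", i, " labels are not balanced")
    x <- feature_matrix(features_list[[i]], log_power)
    fold <- stratified_folds(labels, k_folds, fold_seed + i)
    preps[[i]] <- c(svm_cv_prepare(x, fold, standardize),
                    list(labels = labels,
                         by_fold = split(seq_along(labels), fold)))
    r <- svm_cv_run(preps[[i]], labels, want_weights = FALSE)
    obs[i] <- r$n_correct / r$n_trials
  }
  observed <- mean(obs)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  null_dist <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    acc <- numeric(ns)
    for (i in seq_len(ns)) {
      perm <- preps[[i]]$labels
      for (idx in preps[[i]]$by_fold)
        perm[idx] <- perm[idx[sample.int(length(idx))]]
      r <- svm_cv_run(preps[[i]], perm, want_weights = FALSE)
      acc[i] <- r$n_correct / r$n_trials
    }
    null_dist[it] <- mean(acc)
  }
  list(observed = observed, per_subject = obs,
       null_distribution = null_dist, null_mean = mean(null_dist),
       permutation_p = (1 + sum(null_dist >= observed)) / (1 + n_iterations))
}

#' Frequency-band attribution of classifier weights
#'
#' For every subject whose decoding is individually significant
#' (`binomial_p < p_threshold`), finds the frequency band containing the
#' global maximum of the absolute weight map over channels and in-band
#' frequencies.  Frequencies outside every named band (25-29 Hz) never win.
#' Ties between bands are broken toward the lower-frequency band and
#' reported with a message.
#'
#' @param subject_results List of `subject_decoding` objects with weight
#'   maps on a shared channels x frequencies grid.
#' @param bands Named list of inclusive Hz bounds ([frequency_bands()]).
#' @param p_threshold Per-subject significance filter (set to `Inf` to keep
#'   every subject).
#' @return List with `per_subject` (tibble: subject, binomial_p, included,
#'   band, max_abs_weight) and `counts` (named integer vector over bands,
#'   included subjects only).
#' @export
band_argmax_weights <- function(subject_results, bands = frequency_bands(),
                                p_threshold = 0.05) {
  bands <- bands[order(vapply(bands, `[`, 0, 1))]
  rows <- lapply(seq_along(subject_results), function(i) {
    res <- subject_results[[i]]
    w <- abs(res$weight_map)
    if (all(w == 0)) stop("all-zero weight map for subject ", i)
    freqs <- as.numeric(colnames(res$weight_map))
    band_max <- vapply(bands, function(b) {
      inb <- freqs >= b[1] & freqs <= b[2]
      if (!any(inb)) return(-Inf)
      max(w[, inb])
    }, 0)
    win <- which(band_max == max(band_max))
    if (length(win) > 1)
      message("subject ", i, ": band tie (",
              paste(names(bands)[win], collapse = ", "),
              "), keeping the lower-frequency band")
    tibble::tibble(subject = i, binomial_p = res$binomial_p,
                   included = res$binomial_p < p_threshold,
                   band = names(bands)[win[1]],
                   max_abs_weight = max(band_max))
  })
  per_subject <- do.call(rbind, rows)
  inc <- per_subject[per_subject$included, ]
  counts <- table(factor(inc$band, levels = names(bands)))
  list(per_subject = per_subject,
       counts = setNames(as.integer(counts), names(counts)))
}

#' Stimulation-site lateralization ANOVA
#'
#' Mixed two-way ANOVA of mean high-gamma classifier weights at the lateral
#' central electrodes: stimulation site (left/right hand) as the
#' between-subject factor and electrode (C5/C6) as the within-subject
#' factor.  Returns the site x electrode interaction, the test of whether
#' the weight asymmetry mirrors the stimulated side (df1 = 1,
#' df2 = N - 2).  A perfectly crossed noise-free pattern has zero residual
#' variance; the F statistic is then reported as `Inf` with p = 0.
#'
#' @param weights_c5,weights_c6 Per-subject mean high-gamma weights at C5
#'   and C6.
#' @param site Per-subject `"left"` / `"right"`.
#' @return List `(F, df1, df2, p)`.
#' @export
lateralization_anova <- function(weights_c5, weights_c6, site) {
  n <- length(site)
  stopifnot(length(weights_c5) == n, length(weights_c6) == n)
  if (min(table(factor(site, levels = c("left", "right")))) < 2)
    stop("need at least 2 subjects per stimulation site")
  d <- data.frame(
    weight = c(weights_c5, weights_c6),
    electrode = factor(rep(c("C5", "C6"), each = n)),
    site = factor(rep(site, 2)),
    subject = factor(rep(seq_len(n), 2))
  )
  a <- aov(weight ~ site * electrode + Error(subject / electrode), data = d)
  s <- summary(a)
  within <- s[["Error: subject:electrode"]][[1]]
  row <- trimws(rownames(within)) == "site:electrode"
  ss_int <- within[row, "Sum Sq"]
  ss_res <- within[trimws(rownames(within)) == "Residuals", "Sum Sq"]
  fval <- within[row, "F value"]
  pval <- within[row, "Pr(>F)"]
  # guard the degenerate corners aov leaves to floating point: no residual
  # variance means either no interaction at all (F = 0) or a perfectly
  # crossed pattern (unbounded F)
  if (ss_res <= max(ss_int, 1) * 1e-12) {
    if (ss_int <= 1e-24) {
      fval <- 0; pval <- 1
    } else {
      fval <- Inf; pval <- 0
    }
  }
  list(F = fval, df1 = 1, df2 = n - 2, p = pval)
}

#' Pearson correlation of per-subject pre- and post-stimulus accuracies
#'
#' @param pre_acc,post_acc Per-subject decoding accuracies (n >= 3).
#' @return List `(r, p, n)` (two-sided t-based p).
#' @export
accuracy_correlation <- function(pre_acc, post_acc) {
  pearson_cor(pre_acc, post_acc)
}

pearson_cor <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("need at least 3 subjects")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

# per-subject mean power at one channel over an inclusive frequency band
subject_band_power <- function(features, channel, band = "high_gamma") {
  stopifnot(inherits(features, "spectral_features"))
  if (!channel %in% features$channel_labels)
    stop("channel '", channel, "' not found in the montage")
  sel <- band_select(features, band)
  ci <- match(channel, sel$channel_labels)
  mean(sel$power[, ci, , drop = FALSE])
}

#' Per-trial band power series at one channel
#'
#' Mean power over an inclusive frequency band at a single channel, one
#' value per trial -- the series whose trial-to-trial autocorrelation
#' [trial_autocorrelation()] examines.
#'
#' @param features A [spectral_features()] object.
#' @param channel Channel label (default `"FCz"`).
#' @param band Band name or Hz pair (default `"high_gamma"`).
#' @return Numeric vector, one value per trial.
#' @export
band_power_series <- function(features, channel = "FCz",
                              band = "high_gamma") {
  stopifnot(inherits(features, "spectral_features"))
  if (!channel %in% features$channel_labels)
    stop("channel '", channel, "' not found in the montage")
  sel <- band_select(features, band)
  ci <- match(channel, sel$channel_labels)
  rowMeans(sel$power[, ci, , drop = FALSE], dims = 1)
}

#' Correlation of pre- and post-stimulus high-gamma power at one channel
#'
#' Across subjects, correlates the subject-mean band power (default
#' 60-120 Hz at FCz) between the pre- and post-stimulus windows -- the
#' univariate check that the pre-stimulus gamma state carries over into
#' stimulus processing.
#'
#' @param pre_features_list,post_features_list Per-subject
#'   [spectral_features()] for the two windows.
#' @param channel Channel label (default `"FCz"`).
#' @param band Band name or Hz pair (default `"high_gamma"`).
#' @return List `(r, p, n, pre_power, post_power)`.
#' @export
fcz_gamma_correlation <- function(pre_features_list, post_features_list,
                                  channel = "FCz", band = "high_gamma") {
  pre <- vapply(pre_features_list, subject_band_power, 0, channel, band)
  post <- vapply(post_features_list, subject_band_power, 0, channel, band)
  out <- pearson_cor(pre, post)
  out$pre_power <- pre
  out$post_power <- post
  out
}

#' Per-frequency pre/post power correlation with Bonferroni flags
#'
#' For every grid frequency, correlates subject-mean pre- and post-stimulus
#' power at one channel across subjects; a frequency is flagged significant
#' when its p-value is below `alpha / n_frequencies` (Bonferroni over the
#' grid).
#'
#' @inheritParams fcz_gamma_correlation
#' @param alpha Family-wise error level before correction (default 0.05).
#' @return Tibble with columns `frequency`, `r`, `p`, `significant`;
#'   attribute `"bonferroni_threshold"` holds the per-test level.
#' @export
per_frequency_correlation <- function(pre_features_list, post_features_list,
                                      channel = "FCz", alpha = 0.05) {
  freq <- pre_features_list[[1]]$freq_axis
  if (!identical(freq, post_features_list[[1]]$freq_axis))
    stop("pre and post features must share the frequency grid")
  n_sub <- length(pre_features_list)
  if (n_sub < 3) stop("need at least 3 subjects")
  per_subject_freq <- function(features, channel) {
    if (!channel %in% features$channel_labels)
      stop("channel '", channel, "' not found in the montage")
    ci <- match(channel, features$channel_labels)
    m <- features$power[, ci, , drop = FALSE]
    colMeans(matrix(m, dim(m)[1], dim(m)[3]))
  }
  pre <- t(vapply(pre_features_list, per_subject_freq, numeric(length(freq)),
                  channel))
  post <- t(vapply(post_features_list, per_subject_freq,
                   numeric(length(freq)), channel))
  thr <- alpha / length(freq)
  rows <- lapply(seq_along(freq), function(j) {
    ct <- pearson_cor(pre[, j], post[, j])
    tibble::tibble(frequency = freq[j], r = ct$r, p = ct$p,
                   significant = ct$p < thr)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni_threshold") <- thr
  out
}

#' Trial-to-trial autocorrelation of a band-power series
#'
#' Sample autocorrelation of the per-trial pre-stimulus band-power series
#' at lags `1..max_lag`, with each lag flagged when it exceeds the
#' large-sample white-noise 95% confidence bound `1.96 / sqrt(N)` in
#' absolute value -- the check of whether the pre-stimulus gamma state
#' persists across trials or is trial-specific.
#'
#' @param series Per-trial power values (length > `max_lag + 2`).
#' @param max_lag Largest lag (default 20).
#' @return Tibble with columns `lag`, `acf`, `flagged`; attribute
#'   `"ci_bound"` holds the confidence bound.
#' @export
trial_autocorrelation <- function(series, max_lag = 20) {
  n <- length(series)
  if (n <= max_lag + 2) stop("series too short for max_lag = ", max_lag)
  if (sd(series) == 0) stop("constant series has no autocorrelation")
  ac <- acf(series, lag.max = max_lag, plot = FALSE)$acf[-1]
  bound <- 1.96 / sqrt(n)
  out <- tibble::tibble(lag = seq_len(max_lag), acf = as.numeric(ac),
                        flagged = abs(ac) > bound)
  attr(out, "ci_bound") <- bound
  out
}
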