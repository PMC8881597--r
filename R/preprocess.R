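#' Construct a trial set
#'
#' Container for epoched multichannel EEG: a trials x channels x samples
#' array plus aligned per-trial metadata.  Usually produced by
#' [epoch_trials()] rather than called directly.
#'
#' @param data Numeric array, trials x channels x samples (uV).
#' @param time_axis Numeric vector of sample times in seconds relative to
#'   stimulus onset (length = third array dimension).
#' @param channel_labels Character vector (length = second dimension).
#' @param ratings Per-trial VAS ratings.
#' @param condition Per-trial factor with levels `nopain`, `pain`,
#'   `unassigned`.
#' @param site Stimulation site, `"left"` or `"right"`.
#' @param sampling_rate Hz.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, time_axis, channel_labels, ratings,
                      condition = NULL, site = NA_character_,
                      sampling_rate) {
  stopifnot(length(dim(data)) == 3)
  n_trials <- dim(data)[1]
  if (is.null(condition))
    condition <- factor(rep("unassigned", n_trials),
                        levels = c("nopain", "pain", "unassigned"))
  condition <- factor(as.character(condition),
                      levels = c("nopain", "pain", "unassigned"))
  if (dim(data)[2] != length(channel_labels))
    stop("channel_labels length does not match data")
  if (dim(data)[3] != length(time_axis))
    stop("time_axis length does not match data")
  if (length(ratings) != n_trials || length(condition) != n_trials)
    stop("per-trial metadata must align 1:1 with trials")
  structure(list(data = data, time_axis = time_axis,
                 channel_labels = channel_labels, ratings = ratings,
                 condition = condition, site = site,
                 sampling_rate = sampling_rate),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials x %d channels x %d samples, t in [%.3f, %.3f] s @ %g Hz\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$time_axis), max(x$time_axis), x$sampling_rate))
  tab <- table(x$condition)
  cat("  conditions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

n_trials <- function(ts) dim(ts$data)[1]

# subset trials, keeping metadata aligned
trial_subset <- function(ts, idx) {
  trial_set(ts$data[idx, , , drop = FALSE], ts$time_axis, ts$channel_labels,
            ts$ratings[idx], ts$condition[idx], ts$site, ts$sampling_rate)
}

# Sample-index arithmetic: a window [a, b) in seconds maps to the 0-based
# offsets round(a * rate) .. round(a * rate) + round((b - a) * rate) - 1,
# so the sample count is round(width * rate) (round half to even).
window_offsets <- function(window, rate) {
  i0 <- as.integer(round(window[1] * rate))
  n <- as.integer(round(diff(window) * rate))
  list(start = i0, n = n)
}

#' Epoch a continuous recording around stimulus events
#'
#' Cuts the continuous signal into per-event epochs over `window` seconds
#' relative to each stimulus onset, using 0-based half-open \[start, end)
#' sample windows: the epoch covers sample offsets
#' `round(start * rate) .. round(start * rate) + round((end - start) * rate) - 1`
#' relative to the onset sample, and the onset maps to time 0.
#'
#' @param recording A `subject_recording` (see [generate_subject()]).
#' @param window Length-2 numeric, epoch limits in seconds (default
#'   `c(-2, 2)`).
#' @return A [trial_set()] with one trial per event (condition
#'   `unassigned`).
#' @export
epoch_trials <- function(recording, window = c(-2, 2)) {
  stopifnot(inherits(recording, "subject_recording"))
  if (diff(window) <= 0) stop("window must be increasing")
  rate <- recording$sampling_rate
  off <- window_offsets(window, rate)
  ev <- recording$event_samples
  first <- ev + off$start
  last <- first + off$n - 1L
  bad <- first < 1L | last > ncol(recording$signal)
  if (any(bad))
    stop("events too close to the recording edge for the requested window: ",
         paste(which(bad), collapse = ", "))
  n_ev <- length(ev)
  n_ch <- nrow(recording$signal)
  data <- array(0, dim = c(n_ev, n_ch, off$n))
  for (t in seq_len(n_ev))
    data[t, , ] <- recording$signal[, first[t]:last[t]]
  trial_set(data,
            time_axis = (off$start + seq_len(off$n) - 1L) / rate,
            channel_labels = recording$montage,
            ratings = recording$ratings,
            site = recording$site,
            sampling_rate = rate)
}

#' Analysis windows
#'
#' The two windows the decoding pipeline compares: the pre-stimulus interval
#' \[-1.5, -0.25) s, chosen to exclude any stimulus processing, and the
#' post-stimulus interval \[0, 1) s.
#'
#' @return Named list of length-2 numeric vectors (seconds).
#' @export
analysis_windows <- function() {
  list(pre = c(-1.5, -0.25), post = c(0, 1))
}

#' Extract an analysis sub-window from epoched trials
#'
#' @param trials A [trial_set()].
#' @param period `"pre"`, `"post"` (see [analysis_windows()]) or an explicit
#'   length-2 numeric window in seconds.
#' @return A [trial_set()] restricted to the sub-window; at 250 Hz the pre
#'   window has 312 samples and the post window 250.
#' @export
extract_window <- function(trials, period = c("pre", "post")) {
  stopifnot(inherits(trials, "trial_set"))
  win <- if (is.character(period)) {
    period <- match.arg(period)
    analysis_windows()[[period]]
  } else as.numeric(period)
  rate <- trials$sampling_rate
  off <- window_offsets(win, rate)
  epoch_start <- as.integer(round(trials$time_axis[1] * rate))
  j0 <- off$start - epoch_start          # 0-based offset within the epoch
  if (j0 < 0 || j0 + off$n > dim(trials$data)[3])
    stop(sprintf("requested window [%g, %g) s lies outside the epoch [%g, %g] s",
                 win[1], win[2], min(trials$time_axis), max(trials$time_axis)))
  idx <- j0 + seq_len(off$n)
  out <- trials
  out$data <- trials$data[, , idx, drop = FALSE]
  out$time_axis <- trials$time_axis[idx]
  out
}

#' Automatic per-trial artifact metrics
#'
#' Computes, for every trial, z-scored summaries of the three signatures
#' screened for in routine EEG cleaning: ocular activity (1-15 Hz band
#' power), muscle activity (100-120 Hz band power) and sample-to-sample
#' jumps (maximum absolute first difference).  Band power is the variance of
#' the band-limited signal (via Parseval on the trial FFT), summed over
#' channels; the jump metric is the maximum over channels and samples.  Each
#' metric is z-scored across trials, so it has mean 0 and SD 1 by
#' construction.
#'
#' @param trials A [trial_set()] with at least 2 trials.
#' @return An object of class `artifact_metrics`: a tibble with columns
#'   `trial`, `z_low` (1-15 Hz), `z_high` (100-120 Hz), `z_jump`.
#' @export
artifact_metrics <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  nt <- n_trials(trials)
  if (nt < 2) stop("need at least 2 trials to z-score artifact metrics")
  low <- numeric(nt); high <- numeric(nt); jump <- numeric(nt)
  rate <- trials$sampling_rate
  ns <- dim(trials$data)[3]
  f <- seq(0, rate, length.out = ns + 1)[seq_len(ns)]
  f[f > rate / 2] <- rate - f[f > rate / 2]
  in_low <- f >= 1 & f <= 15
  in_high <- f >= 100 & f <= 120
  for (t in seq_len(nt)) {
    x <- trials$data[t, , , drop = TRUE]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    sp <- Mod(t(mvfft(t(x))))^2 / ns^2   # per-channel FFT energy per bin
    low[t] <- sum(sp[, in_low])
    high[t] <- sum(sp[, in_high])
    jump[t] <- max(abs(x[, -1, drop = FALSE] - x[, -ns, drop = FALSE]))
  }
  zs <- function(v, what) {
    s <- sd(v)
    if (!is.finite(s) || s == 0)
      stop("zero-variance ", what, " metric: degenerate trial set")
    (v - mean(v)) / s
  }
  structure(tibble::tibble(trial = seq_len(nt),
                           z_low = zs(low, "low-band"),
                           z_high = zs(high, "high-band"),
                           z_jump = zs(jump, "jump")),
            class = c("artifact_metrics", class(tibble::tibble())))
}

#' Reject artifact-contaminated trials
#'
#' Removes every trial whose low-band, high-band or jump z-score exceeds
#' `threshold`; contaminated epochs are dropped in their entirety.  The
#' threshold plays the role of the per-dataset cutoff a reviewer would pick
#' interactively; a fixed scalar keeps the pipeline reproducible.
#'
#' @param trials A [trial_set()].
#' @param metrics The matching [artifact_metrics()].
#' @param threshold Positive rejection threshold in z units (default 4).
#' @return The surviving [trial_set()], with attribute `"rejection"` -- a
#'   tibble (trial, z_low, z_high, z_jump, kept) describing the decision.
#' @export
reject_trials <- function(trials, metrics, threshold = 4) {
  stopifnot(inherits(trials, "trial_set"), inherits(metrics, "artifact_metrics"))
  if (threshold <= 0) stop("threshold must be positive")
  if (nrow(metrics) != n_trials(trials))
    stop("metrics do not match the trial set")
  keep <- with(metrics, z_low <= threshold & z_high <= threshold &
                 z_jump <= threshold)
  if (!any(keep)) stop("all trials rejected at threshold ", threshold)
  out <- trial_subset(trials, which(keep))
  report <- metrics
  report$kept <- keep
  attr(out, "rejection") <- report
  out
}

#' Split and balance trials into pain and no-pain conditions
#'
#' Labels trials by their VAS rating (> 50 pain, < 50 no pain; 50 itself is
#' not a legal rating), sorts by rating, and takes a matching number of
#' trials from each end of the list until one condition is exhausted: the
#' `m = min(n_pain, n_nopain)` lowest-rated no-pain and `m` highest-rated
#' pain trials are retained, everything in between is dropped.  Ties in
#' rating are broken by original trial order.  The retained trials keep
#' their chronological order.
#'
#' @param trials A [trial_set()].
#' @return A balanced [trial_set()] with `condition` set and
#'   `count(pain) == count(nopain)`.
#' @export
balance_conditions <- function(trials) {
  stopifnot(inherits(trials, "trial_set"))
  r <- trials$ratings
  if (any(r == 50))
    stop("rating equal to 50 found; the scale midpoint cannot be selected")
  pain_idx <- which(r > 50)
  nopain_idx <- which(r < 50)
  if (!length(pain_idx)) stop("no pain trials (rating > 50)")
  if (!length(nopain_idx)) stop("no no-pain trials (rating < 50)")
  m <- min(length(pain_idx), length(nopain_idx))
  # stable order: ties keep original trial order
  keep_nopain <- nopain_idx[order(r[nopain_idx])][seq_len(m)]
  keep_pain <- pain_idx[order(-r[pain_idx])][seq_len(m)]
  keep <- sort(c(keep_nopain, keep_pain))
  out <- trial_subset(trials, keep)
  out$condition <- factor(ifelse(out$ratings > 50, "pain", "nopain"),
                          levels = c("nopain", "pain", "unassigned"))
  attr(out, "kept") <- keep
  out
}

# subset a spectral_features object by trial index, metadata kept aligned
features_subset <- function(features, idx) {
  stopifnot(inherits(features, "spectral_features"))
  out <- features
  out$power <- features$power[idx, , , drop = FALSE]
  out$ratings <- features$ratings[idx]
  out$condition <- features$condition[idx]
  out
}
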