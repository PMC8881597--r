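#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers for a window of `n_samples` samples at
#' `rate` Hz with spectral concentration half-bandwidth `half_bandwidth` Hz,
#' via the classical symmetric tridiagonal eigenproblem (the tridiagonal
#' matrix that commutes with the concentration operator), so the tapers are
#' exactly orthonormal.  The number of well-concentrated tapers is
#' `round(2 * NW) - 1` with time-bandwidth product
#' `NW = (n_samples / rate) * half_bandwidth`; requesting more than that
#' warns (leakage grows) but does not fail.
#'
#' Signs follow the usual convention that the dominant lobe in the first
#' half of the window is positive; the first taper has no sign changes.
#'
#' @param n_samples Window length in samples (>= 2).
#' @param half_bandwidth Smoothing half-bandwidth in Hz.
#' @param rate Sampling rate in Hz.
#' @param k Number of tapers (> 0).
#' @return A `k x n_samples` matrix with orthonormal rows.
#' @export
#' @examples
#' h <- dpss_tapers(312, 4, 250, 9)   # NW = 4.992, 9 usable tapers
#' max(abs(tcrossprod(h) - diag(9)))
dpss_tapers <- function(n_samples, half_bandwidth, rate, k) {
  if (k <= 0) stop("k must be positive")
  n_samples <- as.integer(n_samples)
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (k > n_samples) stop("cannot compute more tapers than samples")
  nw <- (n_samples / rate) * half_bandwidth
  usable <- max(1, round(2 * nw) - 1)
  if (k > usable)
    warning(sprintf(paste0("requested %d tapers but only %d are well ",
                           "concentrated at NW = %.3f; spectral leakage ",
                           "will increase"), k, usable, nw))
  key <- paste(n_samples, half_bandwidth, rate, k, sep = "|")
  cached <- .dpss_cache[[key]]
  if (!is.null(cached)) return(cached)

  w <- half_bandwidth / rate                 # normalized half-bandwidth
  t_idx <- seq_len(n_samples) - 1
  diag_main <- ((n_samples - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * w)
  off <- t_idx[-1] * (n_samples - t_idx[-1]) / 2
  tri <- diag(diag_main)
  tri[cbind(seq_len(n_samples - 1), seq_len(n_samples - 1) + 1)] <- off
  tri[cbind(seq_len(n_samples - 1) + 1, seq_len(n_samples - 1))] <- off
  eig <- eigen(tri, symmetric = TRUE)
  tapers <- t(eig$vectors[, seq_len(k), drop = FALSE])
  # sign convention: largest-magnitude element of the first half positive
  half <- seq_len(ceiling(n_samples / 2))
  for (i in seq_len(k)) {
    j <- half[which.max(abs(tapers[i, half]))]
    if (tapers[i, j] < 0) tapers[i, ] <- -tapers[i, ]
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

.dpss_cache <- new.env(parent = emptyenv())

#' Frequency bands
#'
#' The canonical band partition used for weight attribution: theta 4-7,
#' alpha 8-12, beta 13-24, low gamma 30-59, high gamma 60-120 Hz (bounds
#' inclusive).  The 25-29 Hz strip belongs to no named band; it is retained
#' in full-spectrum decoding but excluded from band attribution.
#'
#' @return Named list of inclusive Hz bounds.
#' @export
frequency_bands <- function() {
  list(theta = c(4, 7), alpha = c(8, 12), beta = c(13, 24),
       low_gamma = c(30, 59), high_gamma = c(60, 120))
}

#' Multitaper power spectra of epoched trials
#'
#' Transforms every trial and channel into a power spectrum on a fixed
#' frequency grid using the DPSS multitaper method: each trial/channel trace
#' is mean-removed, multiplied by each taper, Fourier-transformed at the
#' grid frequencies, and the squared magnitudes are averaged over tapers
#' (and divided by the sampling rate, giving uV^2/Hz).  Power is averaged
#' over the whole window -- pre-stimulus states are not time-locked, so no
#' time-resolved output is produced.
#'
#' The default grid is integer frequencies 4..120 Hz (117 features per
#' channel) with 4 Hz smoothing half-bandwidth and 9 tapers, for both the
#' 312-sample pre-stimulus and the 250-sample post-stimulus window (where
#' only 7 tapers are well concentrated; a warning records the trade-off).
#'
#' @param trials A [trial_set()].
#' @param fmin,fmax Frequency grid limits in Hz (`fmax` at most Nyquist).
#' @param fstep Grid step in Hz.
#' @param half_bandwidth Smoothing half-bandwidth in Hz.
#' @param k Number of tapers.
#' @param window_id Label stored with the result (e.g. `"pre"`).
#' @return An object of class `spectral_features`: a list with `power`
#'   (trials x channels x frequencies), `freq_axis`, `channel_labels`,
#'   `window_id`, `taper_count`, `smoothing_halfwidth`, and the trial
#'   metadata (`ratings`, `condition`, `site`) carried over.
#' @export
multitaper_power <- function(trials, fmin = 4, fmax = 120, fstep = 1,
                             half_bandwidth = 4, k = 9,
                             window_id = "pre") {
  stopifnot(inherits(trials, "trial_set"))
  nt <- n_trials(trials)
  if (nt == 0) stop("empty trial set")
  rate <- trials$sampling_rate
  if (fmax > rate / 2) stop("fmax exceeds the Nyquist frequency")
  ns <- dim(trials$data)[3]
  nc <- dim(trials$data)[2]
  freq <- seq(fmin, fmax, by = fstep)
  tapers <- dpss_tapers(ns, half_bandwidth, rate, k)
  # DFT basis at the grid frequencies (not restricted to FFT bins)
  basis <- exp(-2i * pi * outer(freq, (seq_len(ns) - 1) / rate))
  # flatten trials x channels into columns of an ns x (nt*nc) matrix
  x <- matrix(aperm(trials$data, c(3, 1, 2)), nrow = ns)
  x <- sweep(x, 2, colMeans(x))
  acc <- matrix(0, length(freq), ncol(x))
  for (i in seq_len(k))
    acc <- acc + Mod(basis %*% (x * tapers[i, ]))^2
  acc <- acc / (k * rate)
  power <- array(t(acc), dim = c(nt, nc, length(freq)))
  dimnames(power) <- list(NULL, trials$channel_labels, freq)
  structure(list(power = power, freq_axis = freq,
                 channel_labels = trials$channel_labels,
                 window_id = window_id, taper_count = k,
                 smoothing_halfwidth = half_bandwidth,
                 ratings = trials$ratings, condition = trials$condition,
                 site = trials$site),
            class = "spectral_features")
}

#' @export
print.spectral_features <- function(x, ...) {
  cat(sprintf("<spectral_features> %s window: %d trials x %d channels x %d frequencies (%g-%g Hz), %d tapers\n",
              x$window_id, dim(x$power)[1], dim(x$power)[2], dim(x$power)[3],
              min(x$freq_axis), max(x$freq_axis), x$taper_count))
  invisible(x)
}

#' Restrict spectral features to a frequency band
#'
#' @param features A [spectral_features()] object.
#' @param band A band name from [frequency_bands()] or an explicit length-2
#'   numeric Hz range (inclusive bounds).
#' @return The features restricted to grid frequencies inside the band.
#' @export
band_select <- function(features, band) {
  stopifnot(inherits(features, "spectral_features"))
  bounds <- if (is.character(band)) {
    bl <- frequency_bands()
    if (!band %in% names(bl))
      stop("unknown band '", band, "'; known: ",
           paste(names(bl), collapse = ", "))
    bl[[band]]
  } else as.numeric(band)
  keep <- features$freq_axis >= bounds[1] & features$freq_axis <= bounds[2]
  if (!any(keep))
    stop(sprintf("band [%g, %g] Hz does not intersect the frequency grid",
                 bounds[1], bounds[2]))
  out <- features
  out$power <- features$power[, , keep, drop = FALSE]
  out$freq_axis <- features$freq_axis[keep]
  out
}
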