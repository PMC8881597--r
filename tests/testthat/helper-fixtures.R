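# fixtures are built in code at test time; nothing is read from disk

# independent brute-force multitaper: explicit per-taper, per-frequency DFT
brute_multitaper <- function(x, freqs, rate, tapers) {
  x <- x - mean(x)
  n <- length(x)
  k <- nrow(tapers)
  p <- numeric(length(freqs))
  for (j in seq_along(freqs)) {
    for (i in seq_len(k)) {
      ph <- exp(-2i * pi * freqs[j] * (0:(n - 1)) / rate)
      p[j] <- p[j] + Mod(sum(tapers[i, ] * x * ph))^2
    }
  }
  p / (k * rate)
}


# white-noise trial set with ratings on both sides of the pain threshold
noise_trial_set <- function(n_trials = 12, n_chan = 3, n_samples = 100,
                            rate = 250, seed = 1, ratings = NULL) {
  set.seed(seed)
  data <- array(rnorm(n_trials * n_chan * n_samples),
                dim = c(n_trials, n_chan, n_samples))
  if (is.null(ratings))
    ratings <- rep(c(30, 70), length.out = n_trials)
  trial_set(data,
            time_axis = seq_len(n_samples) / rate,
            channel_labels = paste0("ch", seq_len(n_chan)),
            ratings = ratings,
            site = "left", sampling_rate = rate)
}

# spectral_features built directly from a power array
fake_features <- function(power, freq_axis,
                          channels = paste0("ch", seq_len(dim(power)[2])),
                          window_id = "pre") {
  structure(list(power = power, freq_axis = freq_axis,
                 channel_labels = channels, window_id = window_id,
                 taper_count = 9, smoothing_halfwidth = 4,
                 ratings = rep(NA_real_, dim(power)[1]),
                 condition = factor(rep("unassigned", dim(power)[1]),
                                    levels = c("nopain", "pain", "unassigned")),
                 site = "left"),
            class = "spectral_features")
}

# gaussian two-class feature matrix wrapped as spectral features, with a
# standardized mean difference `d` planted at the given channel/frequency
planted_features <- function(n_per_class = 40, n_chan = 4, freqs = 4:20,
                             channel = 3, frequency = 10, d = 0, seed = 1) {
  set.seed(seed)
  nf <- length(freqs)
  n <- 2 * n_per_class
  power <- array(exp(rnorm(n * n_chan * nf, sd = 0.5)),
                 dim = c(n, n_chan, nf))
  labels <- rep(c("nopain", "pain"), each = n_per_class)
  j <- match(frequency, freqs)
  power[labels == "pain", channel, j] <-
    power[labels == "pain", channel, j] * exp(d * 0.5)
  list(features = fake_features(power, freqs), labels = labels)
}

# preprocess one generated subject up to balanced spectra
subject_features <- function(rec, window = "pre", threshold = 4) {
  ts <- epoch_trials(rec)
  ts <- reject_trials(ts, artifact_metrics(ts), threshold)
  bal <- balance_conditions(ts)
  f <- if (window == "post")
    suppressWarnings(multitaper_power(extract_window(ts, "post"),
                                      window_id = "post"))
  else multitaper_power(extract_window(ts, "pre"))
  list(features = features_subset(f, attr(bal, "kept")),
       all_features = f,
       labels = as.character(bal$condition),
       site = rec$site)
}

features_subset <- prestim:::features_subset
trial_subset <- prestim:::trial_subset
n_trials <- prestim:::n_trials

# multiset difference: remove one occurrence of each element of y from x
setdiff_multiset <- function(x, y) {
  for (v in y) {
    i <- match(v, x)
    if (!is.na(i)) x <- x[-i]
  }
  x
}

# one default-effect cohort analysed once and shared across acceptance
# blocks (decoding three ranges, permutation null, lateralization inputs)
.effect_cache <- new.env(parent = emptyenv())
effect_cohort_analysis <- function() {
  if (!is.null(.effect_cache$res)) return(.effect_cache$res)
  cfg <- cohort_config(n_subjects = 10, n_trials_per_condition = 40,
                       montage = montage_16(), seed = 1)
  cohort <- generate_cohort(cfg)
  feats <- lapply(cohort, subject_features)
  full <- hg <- theta <- vector("list", 10)
  for (i in 1:10) {
    full[[i]] <- decode_subject(feats[[i]]$features, feats[[i]]$labels,
                                "full", seed = i)
    hg[[i]] <- decode_subject(feats[[i]]$features, feats[[i]]$labels,
                              "high_gamma", seed = i)
    theta[[i]] <- decode_subject(feats[[i]]$features, feats[[i]]$labels,
                                 "theta", seed = i)
  }
  perm <- permutation_null(lapply(feats, `[[`, "features"),
                           lapply(feats, `[[`, "labels"),
                           n_iterations = 200, seed = 7)
  .effect_cache$res <- list(cfg = cfg, cohort = cohort, feats = feats,
                            full = full, hg = hg, theta = theta, perm = perm,
                            sites = vapply(cohort, `[[`, "", "site"))
  .effect_cache$res
}
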