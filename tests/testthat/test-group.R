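two_subject_features <- function(d = 0, seed = 1) {
  lapply(1:2, function(i)
    planted_features(n_per_class = 15, n_chan = 2, freqs = 4:20,
                     channel = 1, frequency = 10, d = d, seed = seed + i))
}

# a cohort whose classes differ on every feature: decodes perfectly
separable_features <- function(seed) {
  set.seed(seed)
  n <- 30; n_chan <- 2; freqs <- 4:20
  power <- array(exp(rnorm(n * n_chan * length(freqs), sd = 0.1)),
                 dim = c(n, n_chan, length(freqs)))
  labels <- rep(c("nopain", "pain"), each = n / 2)
  power[labels == "pain", , ] <- power[labels == "pain", , ] * exp(3)
  list(features = fake_features(power, freqs), labels = labels)
}

test_that("permutation p follows the add-one counting rule", {
  subs <- lapply(40:41, separable_features)
  pn <- permutation_null(lapply(subs, `[[`, "features"),
                         lapply(subs, `[[`, "labels"),
                         n_iterations = 99, seed = 3)
  expect_equal(pn$observed, 1)               # separable cohort
  expect_equal(pn$permutation_p, 1 / 100)    # nothing ties a perfect score
  expect_length(pn$null_distribution, 99)
})

test_that("the permutation null is reproducible and seed-sensitive", {
  subs <- two_subject_features(d = 1, seed = 50)
  f <- lapply(subs, `[[`, "features"); l <- lapply(subs, `[[`, "labels")
  a <- permutation_null(f, l, n_iterations = 20, seed = 5)
  b <- permutation_null(f, l, n_iterations = 20, seed = 5)
  c2 <- permutation_null(f, l, n_iterations = 20, seed = 6)
  expect_identical(a$null_distribution, b$null_distribution)
  expect_false(identical(a$null_distribution, c2$null_distribution))
  expect_error(permutation_null(f, l, n_iterations = 0), ">= 1")
})

test_that("band attribution matches an exhaustive scan and breaks ties low", {
  mk_res <- function(w, p = 0.01) {
    structure(list(weight_map = w, binomial_p = p,
                   accuracy = 0.8, n_correct = 40, n_trials = 50),
              class = "subject_decoding")
  }
  freqs <- 4:120
  # single nonzero weight at 80 Hz -> high gamma
  w1 <- matrix(0, 2, 117, dimnames = list(c("a", "b"), freqs))
  w1["a", "80"] <- -0.5
  # equal maxima at 5 and 80 Hz -> tie broken toward theta, with a message
  w2 <- w1; w2["b", "5"] <- 0.5
  expect_message(
    ba <- band_argmax_weights(list(mk_res(w1), mk_res(w2))), "tie")
  expect_equal(ba$per_subject$band, c("high_gamma", "theta"))
  expect_equal(unname(ba$counts["high_gamma"]), 1L)
  expect_equal(unname(ba$counts["theta"]), 1L)

  # random maps agree with a brute-force scan over every cell
  set.seed(61)
  bands <- frequency_bands()
  for (i in 1:20) {
    w <- matrix(rnorm(2 * 117), 2, 117, dimnames = list(c("a", "b"), freqs))
    ba1 <- band_argmax_weights(list(mk_res(w)))
    best <- -Inf; winner <- NA
    for (bn in names(bands)) {
      inb <- freqs >= bands[[bn]][1] & freqs <= bands[[bn]][2]
      if (max(abs(w[, inb])) > best) {
        best <- max(abs(w[, inb])); winner <- bn
      }
    }
    expect_equal(ba1$per_subject$band, winner)
  }

  # the significance filter excludes subjects from the counts
  ba2 <- band_argmax_weights(list(mk_res(w1), mk_res(w1, p = 0.5)))
  expect_equal(sum(ba2$counts), 1L)
  expect_error(band_argmax_weights(list(mk_res(0 * w1))), "all-zero")
})

test_that("the lateralization ANOVA matches a closed-form decomposition", {
  # fixed 8-subject example, checked against the textbook sums of squares
  c5 <- c(-0.3, -0.1, -0.25, -0.15, 0.2, 0.3, 0.1, 0.25)
  c6 <- c(0.35, 0.2, 0.15, 0.3, -0.2, -0.35, -0.05, -0.3)
  site <- rep(c("left", "right"), each = 4)
  res <- lateralization_anova(c5, c6, site)

  # oracle: for a 2-level within factor the interaction test reduces to a
  # between-groups ANOVA on the within-subject differences
  d <- c6 - c5
  n <- length(d)
  grand <- mean(d)
  ss_between <- sum(tapply(d, site, function(v) length(v) * (mean(v) - grand)^2))
  ss_within <- sum((d - ave(d, site))^2)
  f_oracle <- (ss_between / 1) / (ss_within / (n - 2))
  expect_equal(res$F, f_oracle, tolerance = 1e-10)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 6)
  expect_equal(res$p, pf(f_oracle, 1, 6, lower.tail = FALSE),
               tolerance = 1e-10)

  # all weights equal -> no interaction at all
  flat <- lateralization_anova(rep(0.2, 8), rep(0.2, 8), site)
  expect_equal(flat$F, 0)

  # perfectly crossed, noise-free pattern -> unbounded F, p -> 0
  perfect <- lateralization_anova(c(-1, -1, 1, 1), c(1, 1, -1, -1),
                                  c("left", "left", "right", "right"))
  expect_true(is.infinite(perfect$F))
  expect_equal(perfect$p, 0)

  expect_error(lateralization_anova(c5[1:3], c6[1:3], c("left", "left", "right")),
               "2 subjects per")
})

test_that("correlations agree with the covariance formula", {
  expect_equal(accuracy_correlation(1:5 / 10, 1:5 / 10)$r, 1)
  expect_equal(accuracy_correlation(1:5, -(1:5))$r, -1)
  set.seed(71)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  res <- accuracy_correlation(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  t_stat <- r_oracle * sqrt(18 / (1 - r_oracle^2))
  expect_equal(res$p, 2 * pt(abs(t_stat), 18, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(accuracy_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(accuracy_correlation(1:2, 2:1), "at least 3")
})

test_that("sampled correlations recover the generating coefficient", {
  set.seed(81)
  rhat <- vapply(1:500, function(i) {
    x <- rnorm(33)
    y <- 0.8 * x + sqrt(1 - 0.64) * rnorm(33)
    cor(x, y)
  }, 0)
  expect_lt(abs(mean(rhat) - 0.8), 0.03)
})

test_that("band power extraction validates channels and bands", {
  power <- array(runif(4 * 2 * 117), dim = c(4, 2, 117))
  f <- fake_features(power, 4:120, channels = c("FCz", "Oz"))
  s <- band_power_series(f, "FCz", "high_gamma")
  expect_length(s, 4)
  expect_equal(s, rowMeans(power[, 1, 57:117]))
  expect_error(band_power_series(f, "Cz"), "not found")
  expect_error(fcz_gamma_correlation(list(f), list(f), channel = "Pz"),
               "not found")
})

test_that("per-frequency correlation applies the Bonferroni rule", {
  set.seed(91)
  n_sub <- 20
  freqs <- 4:120
  mk <- function(vals) fake_features(array(vals, c(1, 1, 117)), freqs,
                                     channels = "FCz")
  # plant coupling only at >= 60 Hz through a shared subject factor
  pre <- list(); post <- list()
  for (i in seq_len(n_sub)) {
    u <- rnorm(1)
    base_pre <- exp(rnorm(117, sd = 0.1))
    base_post <- exp(rnorm(117, sd = 0.1))
    hi <- freqs >= 60
    base_pre[hi] <- base_pre[hi] * exp(u)
    base_post[hi] <- base_post[hi] * exp(u)
    pre[[i]] <- mk(base_pre); post[[i]] <- mk(base_post)
  }
  tab <- per_frequency_correlation(pre, post, channel = "FCz", alpha = 0.05)
  expect_equal(nrow(tab), 117)
  expect_equal(attr(tab, "bonferroni_threshold"), 0.05 / 117)
  expect_true(all(tab$frequency[tab$significant] >= 60))
  expect_gt(sum(tab$significant), 30)
  # flags equal the brute-force comparison p < alpha / 117
  expect_equal(tab$significant, tab$p < 0.05 / 117)
  # alpha = 0 switches everything off
  tab0 <- per_frequency_correlation(pre, post, channel = "FCz", alpha = 0)
  expect_false(any(tab0$significant))
})

test_that("trial autocorrelation recovers AR(1) structure and flags it", {
  set.seed(101)
  n <- 2000
  x <- numeric(n); x[1] <- rnorm(1)
  for (t in 2:n) x[t] <- 0.5 * x[t - 1] + rnorm(1)
  tab <- trial_autocorrelation(x, max_lag = 20)
  expect_equal(nrow(tab), 20)
  expect_lt(abs(tab$acf[1] - 0.5), 0.05)
  expect_true(tab$flagged[1])
  expect_equal(attr(tab, "ci_bound"), 1.96 / sqrt(n))
  expect_error(trial_autocorrelation(rep(1, 100)), "constant")
  expect_error(trial_autocorrelation(rnorm(10), max_lag = 20), "too short")
})

test_that("white-noise series are flagged at the nominal 5% rate", {
  set.seed(111)
  rates <- vapply(1:500, function(i) {
    tab <- trial_autocorrelation(rnorm(80), max_lag = 20)
    mean(tab$flagged)
  }, 0)
  expect_lt(abs(mean(rates) - 0.05), 0.015)
})
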