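make_recording <- function(signal, events, ratings, rate = 250,
                           montage = paste0("ch", seq_len(nrow(signal)))) {
  structure(list(signal = signal, sampling_rate = rate,
                 event_samples = as.integer(events), ratings = ratings,
                 site = "left", montage = montage,
                 subject_index = 1L, ground_truth = NULL),
            class = "subject_recording")
}

test_that("epoching uses half-open sample windows with rounded counts", {
  # 2 s epoch at 250 Hz -> 1000 samples; constant-zero signal stays zero
  sig <- matrix(0, 2, 3000)
  rec <- make_recording(sig, events = c(600, 1800), ratings = c(30, 70))
  ts <- epoch_trials(rec, c(-2, 2))
  expect_equal(dim(ts$data), c(2, 2, 1000))
  expect_true(all(ts$data == 0))
  expect_equal(ts$time_axis[1], -2)

  # single event, window [-1.5, -0.25): 0-based half-open source range
  # [4625, 4937), i.e. 312 samples starting at 1-based index 4626
  sig <- matrix(seq_len(6000), 1, 6000)   # signal value = 1-based index
  rec <- make_recording(sig, events = 5001, ratings = 60)
  ts <- epoch_trials(rec, c(-1.5, -0.25))
  expect_equal(dim(ts$data)[3], 312)
  expect_equal(as.numeric(ts$data[1, 1, ]), 4626:4937)
})

test_that("epoching rejects events too close to the recording edge", {
  sig <- matrix(0, 1, 2000)
  rec <- make_recording(sig, events = c(300, 1000, 1900), ratings = c(30, 70, 30))
  expect_error(epoch_trials(rec, c(-2, 2)), "1, 3")
})

test_that("analysis sub-windows have the documented sample counts", {
  rec <- make_recording(matrix(rnorm(4000), 2, 2000), events = 1000,
                        ratings = 60)
  ts <- epoch_trials(rec, c(-2, 2))
  expect_equal(dim(extract_window(ts, "pre")$data)[3], 312)
  expect_equal(dim(extract_window(ts, "post")$data)[3], 250)
  # pre window starts at -1.5 s exactly
  expect_equal(extract_window(ts, "pre")$time_axis[1], -1.5)
  # an epoch starting at -1 s cannot contain the pre window
  short <- epoch_trials(rec, c(-1, 2))
  expect_error(extract_window(short, "pre"), "outside the epoch")
  # explicit windows are accepted
  expect_equal(dim(extract_window(ts, c(0, 0.5))$data)[3], 125)
})

test_that("artifact metrics are z-scored per trial and flag constructions", {
  ts <- noise_trial_set(n_trials = 20, n_chan = 2, n_samples = 500, seed = 4)
  m <- artifact_metrics(ts)
  for (col in c("z_low", "z_high", "z_jump")) {
    expect_equal(mean(m[[col]]), 0, tolerance = 1e-12)
    expect_equal(sd(m[[col]]), 1, tolerance = 1e-12)
  }
  # a 200 uV single-sample step dominates the jump metric
  ts$data[7, 1, 250] <- ts$data[7, 1, 250] + 200
  m2 <- artifact_metrics(ts)
  expect_equal(which.max(m2$z_jump), 7L)

  # identical trials have no variance to z-score
  flat <- ts
  for (t in seq_len(20)) flat$data[t, , ] <- ts$data[1, , ]
  expect_error(artifact_metrics(flat), "zero-variance")
  expect_error(artifact_metrics(trial_subset(ts, 1)), "at least 2")
})

test_that("band metrics respond to the band they are named for", {
  rate <- 250; ns <- 500
  tt <- seq_len(ns) / rate
  data <- array(rnorm(20 * 1 * ns, sd = 0.1), dim = c(20, 1, ns))
  data[3, 1, ] <- data[3, 1, ] + 20 * sin(2 * pi * 8 * tt)     # EOG band
  data[5, 1, ] <- data[5, 1, ] + 20 * sin(2 * pi * 110 * tt)   # muscle band
  ts <- trial_set(data, tt, "ch1", ratings = rep(c(30, 70), 10),
                  sampling_rate = rate)
  m <- artifact_metrics(ts)
  expect_equal(which.max(m$z_low), 3L)
  expect_equal(which.max(m$z_high), 5L)
})

test_that("trial rejection matches a brute-force filter over the metrics", {
  ts <- noise_trial_set(n_trials = 40, n_chan = 2, n_samples = 200, seed = 9)
  m <- artifact_metrics(ts)
  expect_equal(n_trials(reject_trials(ts, m, Inf)), 40)

  kept <- reject_trials(ts, m, 2)
  brute <- which(!(m$z_low > 2 | m$z_high > 2 | m$z_jump > 2))
  expect_equal(n_trials(kept), length(brute))
  expect_equal(kept$ratings, ts$ratings[brute])
  expect_equal(kept$data, ts$data[brute, , , drop = FALSE])
  expect_error(reject_trials(ts, m, -1), "positive")
  hopeless <- m
  hopeless$z_low <- hopeless$z_low + 100   # every trial now exceeds any cut
  expect_error(reject_trials(ts, hopeless, 4), "all trials rejected")
})

test_that("an injected artifact trial is removed in its entirety", {
  ts <- noise_trial_set(n_trials = 10, n_chan = 2, n_samples = 200, seed = 2)
  ts$data[4, 2, 100] <- ts$data[4, 2, 100] + 500
  m <- artifact_metrics(ts)
  # only the injected trial crosses z = 2 on any metric
  crossers <- which(m$z_low > 2 | m$z_high > 2 | m$z_jump > 2)
  expect_equal(crossers, 4L)
  kept <- reject_trials(ts, m, 2)
  expect_equal(n_trials(kept), 9)
  expect_equal(kept$ratings, ts$ratings[-4])
})

test_that("balancing follows the sort-and-take-ends rule", {
  ts6 <- noise_trial_set(n_trials = 6, ratings = c(10, 30, 45, 55, 70, 90))
  bal <- balance_conditions(ts6)
  expect_equal(sort(bal$ratings), c(10, 30, 45, 55, 70, 90))
  expect_equal(as.character(table(bal$condition)[c("nopain", "pain")]),
               c("3", "3"))

  ts4 <- noise_trial_set(n_trials = 4, ratings = c(10, 55, 60, 70))
  bal4 <- balance_conditions(ts4)
  expect_equal(sort(bal4$ratings), c(10, 70))

  expect_error(balance_conditions(
    noise_trial_set(n_trials = 4, ratings = c(60, 70, 80, 90))), "no no-pain")
  expect_error(balance_conditions(
    noise_trial_set(n_trials = 4, ratings = c(10, 20, 30, 40))), "no pain")
  expect_error(balance_conditions(
    noise_trial_set(n_trials = 4, ratings = c(10, 50, 60, 70))), "50")
})

test_that("balancing selects extreme ratings, is idempotent and stable", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:30, 1)
    ratings <- sample(c(1:49, 51:100), n, replace = TRUE)
    ts <- noise_trial_set(n_trials = n, ratings = ratings, seed = rep)
    if (!any(ratings < 50) || !any(ratings > 50)) next
    bal <- balance_conditions(ts)
    keep_no <- sort(bal$ratings[bal$condition == "nopain"])
    keep_pa <- sort(bal$ratings[bal$condition == "pain"])
    expect_equal(length(keep_no), length(keep_pa))
    # selected no-pain ratings are all <= every excluded no-pain rating
    excl_no <- setdiff_multiset(ratings[ratings < 50], keep_no)
    if (length(excl_no)) expect_lte(max(keep_no), min(excl_no))
    excl_pa <- setdiff_multiset(ratings[ratings > 50], keep_pa)
    if (length(excl_pa)) expect_gte(min(keep_pa), max(excl_pa))
    # idempotence
    bal2 <- balance_conditions(bal)
    expect_equal(bal2$data, bal$data)
    expect_equal(bal2$ratings, bal$ratings)
  }
})

test_that("rejection then balancing commutes with trial reordering", {
  ts <- noise_trial_set(n_trials = 24, n_chan = 2, n_samples = 200, seed = 6,
                        ratings = sample(c(1:49, 51:100), 24))
  perm <- sample(24)
  tsp <- trial_subset(ts, perm)
  pipeline <- function(x) {
    kept <- reject_trials(x, artifact_metrics(x), 2.5)
    balance_conditions(kept)
  }
  a <- pipeline(ts); b <- pipeline(tsp)
  expect_equal(sort(a$ratings), sort(b$ratings))
})
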