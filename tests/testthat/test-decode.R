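test_that("standardization is train-fitted and matches the direct formula", {
  set.seed(1)
  tr <- matrix(rnorm(24), 6, 4)
  te <- matrix(rnorm(12), 3, 4)
  st <- standardize_features(tr, te)
  for (j in 1:4) {
    mu <- mean(tr[, j]); s <- sd(tr[, j])
    expect_equal(st$train[, j], (tr[, j] - mu) / s, tolerance = 1e-12)
    expect_equal(st$test[, j], (te[, j] - mu) / s, tolerance = 1e-12)
  }
  expect_equal(colMeans(st$train), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(st$train, 2, sd), rep(1, 4), tolerance = 1e-12)

  tr[, 2] <- 5   # constant feature
  expect_warning(st2 <- standardize_features(tr, te), "constant")
  expect_true(all(st2$train[, 2] == 0))
  expect_true(all(st2$test[, 2] == 0))
})

test_that("binomial test equals the exact tail sum for all n <= 200", {
  # independent oracle: direct summation of binomial probabilities
  oracle <- function(k, n) sum(choose(n, k:n)) / 2^n
  expect_equal(binomial_test(10, 10), 2^-10)
  expect_equal(binomial_test(0, 10), 1)
  expect_equal(binomial_test(40, 80), oracle(40, 80), tolerance = 1e-12)
  worst <- 0
  for (n in 1:200) {
    k <- c(0, floor(n / 2), n)
    for (ki in k)
      worst <- max(worst, abs(binomial_test(ki, n) - oracle(ki, n)))
  }
  expect_lt(worst, 1e-12)
})

test_that("well-separated clusters decode perfectly", {
  # classes separated by ~10 within-class SDs on every feature
  set.seed(2)
  power <- array(exp(rnorm(80 * 4 * 17, sd = 0.3)), dim = c(80, 4, 17))
  labels <- rep(c("nopain", "pain"), each = 40)
  power[labels == "pain", , ] <- power[labels == "pain", , ] * exp(3)
  pf <- list(features = fake_features(power, 4:20), labels = labels)
  res <- svm_crossval(pf$features, pf$labels, seed = 1)
  expect_equal(res$accuracy, 1)
  expect_lt(res$binomial_p, 1e-15)
  expect_equal(res$n_correct, res$n_trials)
  expect_equal(sort(unique(res$fold_assignment)), 1:5)
  # stratified: every fold holds both classes
  for (f in 1:5)
    expect_equal(length(unique(pf$labels[res$fold_assignment == f])), 2)
})

test_that("label-free data decodes at chance on average", {
  accs <- vapply(1:40, function(i) {
    pf <- planted_features(n_per_class = 12, n_chan = 2, freqs = 4:9,
                           channel = 1, frequency = 5, d = 0, seed = 100 + i)
    svm_crossval(pf$features, pf$labels, seed = i)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.04)
})

test_that("a planted univariate effect is recovered in the weight map", {
  hits <- 0; sign_ok <- 0
  for (i in 1:5) {
    pf <- planted_features(n_per_class = 40, n_chan = 4, freqs = 70:90,
                           channel = 2, frequency = 80, d = 3,
                           seed = 200 + i)
    res <- svm_crossval(pf$features, pf$labels, seed = i)
    w <- res$weight_map
    am <- which(abs(w) == max(abs(w)), arr.ind = TRUE)
    if (rownames(w)[am[1]] == "ch2" && colnames(w)[am[2]] == "80")
      hits <- hits + 1
    if (w["ch2", "80"] > 0) sign_ok <- sign_ok + 1   # pain mean is higher
  }
  expect_gte(hits, 4)
  expect_equal(sign_ok, 5)
})

test_that("decoding validates labels and trial counts", {
  pf <- planted_features(n_per_class = 10, seed = 3)
  expect_error(svm_crossval(pf$features, rep("pain", 20)), "balanced")
  expect_error(svm_crossval(pf$features, c(pf$labels[-1], "maybe")), "pain")
  small <- planted_features(n_per_class = 4, seed = 3)
  expect_error(svm_crossval(small$features, small$labels), "2 trials per fold")
})

test_that("the SVD projection is exact against a direct SVM fit", {
  # dual-route check: the pipeline's projected fit vs e1071 on raw features
  pf <- planted_features(n_per_class = 15, n_chan = 3, freqs = 4:40,
                         channel = 1, frequency = 20, d = 1, seed = 11)
  x <- log(prestim:::feature_matrix(pf$features))
  labels <- pf$labels
  fold <- prestim:::stratified_folds(labels, 5, seed = 4)
  prep <- prestim:::svm_cv_prepare(x, fold)
  res <- prestim:::svm_cv_run(prep, labels)
  correct_direct <- 0
  for (f in 1:5) {
    tr <- which(fold != f); te <- which(fold == f)
    st <- standardize_features(x[tr, ], x[te, , drop = FALSE])
    m <- e1071::svm(st$train, factor(labels[tr], c("nopain", "pain")),
                    kernel = "linear", cost = 1, scale = FALSE)
    correct_direct <- correct_direct +
      sum(as.character(predict(m, st$test)) == labels[te])
  }
  expect_equal(res$n_correct, correct_direct)
})

test_that("pooled accuracy is invariant to trial order given matching folds", {
  pf <- planted_features(n_per_class = 15, n_chan = 3, freqs = 4:20,
                         channel = 2, frequency = 10, d = 1, seed = 21)
  x <- log(prestim:::feature_matrix(pf$features))
  fold <- prestim:::stratified_folds(pf$labels, 5, seed = 9)
  r1 <- prestim:::svm_cv_run(prestim:::svm_cv_prepare(x, fold), pf$labels)
  perm <- sample(nrow(x))
  r2 <- prestim:::svm_cv_run(prestim:::svm_cv_prepare(x[perm, ], fold[perm]),
                             pf$labels[perm])
  expect_equal(r1$n_correct, r2$n_correct)
})

test_that("frequency-restricted decoding records its range", {
  pf <- planted_features(n_per_class = 15, freqs = 4:120, channel = 2,
                         frequency = 80, d = 2, seed = 31)
  full <- decode_subject(pf$features, pf$labels, "full", seed = 2)
  explicit <- decode_subject(pf$features, pf$labels, c(4, 120), seed = 2)
  expect_equal(full$accuracy, explicit$accuracy)
  expect_equal(full$weight_map, explicit$weight_map)
  expect_equal(full$frequency_range_used, c(4, 120))

  hg <- decode_subject(pf$features, pf$labels, "high_gamma", seed = 2)
  expect_equal(hg$frequency_range_used, c(60, 120))
  expect_equal(dim(hg$weight_map)[2], 61)
  theta <- decode_subject(pf$features, pf$labels, "theta", seed = 2)
  expect_equal(dim(theta$weight_map)[2], 4)
})

test_that("glance and tidy views of a decoding result are consistent", {
  pf <- planted_features(n_per_class = 10, seed = 5)
  res <- svm_crossval(pf$features, pf$labels, seed = 1)
  g <- glance(res)
  expect_equal(g$accuracy, res$n_correct / res$n_trials)
  td <- tidy(res)
  expect_equal(nrow(td), prod(dim(res$weight_map)))
  expect_equal(sum(abs(td$weight)), sum(abs(res$weight_map)))
})
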