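#' Train-fitted feature standardization
#'
#' Centers and scales every feature column by the mean and standard
#' deviation computed on the training rows only, and applies the same
#' transform to the test rows, so no information leaks from test to train.
#' Features with zero training SD are mapped to zero (with a warning).
#'
#' @param train,test Numeric matrices with the same columns.
#' @return List with standardized `train` and `test` matrices.
#' @export
standardize_features <- function(train, test) {
  mu <- colMeans(train)
  sigma <- apply(train, 2, sd)
  dead <- !is.finite(sigma) | sigma == 0
  if (any(dead)) {
    warning(sum(dead), " constant feature(s) standardized to zero")
    sigma[dead] <- 1
  }
  tr <- sweep(sweep(train, 2, mu), 2, sigma, "/")
  te <- sweep(sweep(test, 2, mu), 2, sigma, "/")
  tr[, dead] <- 0
  te[, dead] <- 0
  list(train = tr, test = te)
}

#' Exact one-sided binomial test against chance
#'
#' Upper-tail probability `P[X >= n_correct]` for
#' `X ~ Binomial(n_trials, 0.5)` -- the significance of a decoding accuracy
#' against the 50% chance level.
#'
#' @param n_correct,n_trials Counts, `0 <= n_correct <= n_trials`.
#' @return The exact p-value.
#' @export
#' @examples
#' binomial_test(10, 10)   # 2^-10
binomial_test <- function(n_correct, n_trials) {
  stopifnot(n_correct >= 0, n_correct <= n_trials)
  pbinom(n_correct - 1, n_trials, 0.5, lower.tail = FALSE)
}

# --- internal SVM machinery -------------------------------------------------

# Stratified fold assignment: within each class, trials are dealt to folds
# 1..k in seeded random order.
stratified_folds <- function(labels, k, seed) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Precompute, per fold, everything that does not depend on the labels:
# standardization parameters and an exact projection of the standardized
# features onto the training row space (via thin SVD).  The linear SVM dual
# depends on the Gram matrix only, so fitting in the projected space gives
# bitwise-identical decisions while the fit cost no longer scales with the
# feature count; weights are mapped back through the projection basis.
svm_cv_prepare <- function(x, fold, standardize = c("per_fold", "global")) {
  standardize <- match.arg(standardize)
  k <- max(fold)
  if (standardize == "global") {
    mu <- colMeans(x)
    sigma <- apply(x, 2, sd)
    sigma[!is.finite(sigma) | sigma == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sigma, "/")
  }
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    xtr <- x[tr_idx, , drop = FALSE]
    xte <- x[te_idx, , drop = FALSE]
    if (standardize == "per_fold") {
      st <- suppressWarnings(standardize_features(xtr, xte))
      xtr <- st$train; xte <- st$test
    }
    sv <- svd(xtr)
    r <- sum(sv$d > max(sv$d[1], .Machine$double.eps) * 1e-10)
    v <- sv$v[, seq_len(r), drop = FALSE]
    folds[[f]] <- list(train = tr_idx, test = te_idx,
                       v = v,
                       ztr = xtr %*% v, zte = xte %*% v)
  }
  list(folds = folds, fold = fold, n_features = ncol(x))
}

# Fit a linear soft-margin SVM (C = 1) on one prepared fold and return the
# held-out decision values (oriented so positive favors "pain") and the
# full-space weight vector.
svm_fold_fit <- function(fp, labels, want_weights = TRUE) {
  y <- factor(labels[fp$train], levels = c("nopain", "pain"))
  if (length(unique(y)) < 2) stop("a training fold contains only one class")
  m <- e1071::svm(fp$ztr, y, kernel = "linear", cost = 1, scale = FALSE)
  wz <- drop(crossprod(m$coefs, m$SV))
  f_tr <- drop(fp$ztr %*% wz) - m$rho
  fitted <- m$fitted
  # orient the decision axis so positive values favor the pain class
  mp <- mean(f_tr[fitted == "pain"]); mn <- mean(f_tr[fitted == "nopain"])
  orient <- if (is.finite(mp) && is.finite(mn)) sign(mp - mn) else 1
  if (orient == 0) orient <- 1
  f_te <- orient * (drop(fp$zte %*% wz) - m$rho)
  w <- if (want_weights) orient * drop(fp$v %*% wz) else NULL
  list(decision = f_te, weights = w)
}

svm_cv_run <- function(prep, labels, want_weights = TRUE) {
  n <- length(labels)
  correct <- 0L
  wsum <- if (want_weights) numeric(prep$n_features) else NULL
  for (fp in prep$folds) {
    fit <- svm_fold_fit(fp, labels, want_weights)
    pred <- ifelse(fit$decision > 0, "pain", "nopain")
    correct <- correct + sum(pred == labels[fp$test])
    if (want_weights) wsum <- wsum + fit$weights
  }
  list(n_correct = as.integer(correct), n_trials = n,
       weights = if (want_weights) wsum / length(prep$folds) else NULL)
}

# ---------------------------------------------------------------------------

#' Cross-validated linear SVM decoding of pain vs no-pain
#'
#' Stratified k-fold cross-validation of a linear soft-margin support vector
#' machine (C = 1) on single-trial spectral features.  Within each fold the
#' features are standardized with train-fitted parameters (see
#' [standardize_features()]; set `standardize = "global"` for a single
#' standardization over all trials), the SVM is trained on the training
#' trials, and the held-out trials are predicted; accuracy is pooled over
#' folds and tested against chance with the exact one-sided
#' [binomial_test()].  The per-fold linear weight vectors are averaged and
#' reshaped to a channels x frequencies map, signed so positive weights
#' favor the pain class.
#'
#' @param features A [spectral_features()] object or a trials x features
#'   matrix.
#' @param labels Per-trial labels, `"pain"` / `"nopain"`, balanced.
#' @param k_folds Number of folds (default 5).
#' @param seed Seed for the stratified fold split.
#' @param standardize `"per_fold"` (train-fitted, default) or `"global"`.
#' @param log_power Log-transform spectral power before standardization
#'   (default `TRUE`).  Single-trial power is approximately lognormal, so
#'   the log makes the features near-Gaussian -- the geometry a linear
#'   margin classifier assumes; ignored for plain-matrix input.
#' @return An object of class `subject_decoding` with fields `accuracy`,
#'   `n_correct`, `n_trials`, `fold_assignment`, `binomial_p`,
#'   `weight_map` (channels x frequencies; `NULL` for plain-matrix input
#'   with unknown geometry a plain vector is returned), and
#'   `frequency_range_used`.
#' @export
svm_crossval <- function(features, labels, k_folds = 5, seed = 1,
                         standardize = c("per_fold", "global"),
                         log_power = TRUE) {
  standardize <- match.arg(standardize)
  labels <- as.character(labels)
  if (!all(labels %in% c("pain", "nopain")))
    stop("labels must be 'pain' or 'nopain'")
  tab <- table(labels)
  if (length(tab) != 2 || tab[1] != tab[2])
    stop("labels must be balanced between pain and nopain")
  x <- feature_matrix(features, log_power)
  if (nrow(x) != length(labels)) stop("labels do not match trials")
  if (nrow(x) < 2 * k_folds) stop("need at least 2 trials per fold")
  fold <- stratified_folds(labels, k_folds, seed)
  prep <- svm_cv_prepare(x, fold, standardize)
  res <- svm_cv_run(prep, labels)
  weight_map <- res$weights
  frange <- NULL
  if (inherits(features, "spectral_features")) {
    weight_map <- matrix(res$weights, dim(features$power)[2],
                         dim(features$power)[3],
                         dimnames = list(features$channel_labels,
                                         features$freq_axis))
    frange <- range(features$freq_axis)
  }
  structure(list(accuracy = res$n_correct / res$n_trials,
                 n_correct = res$n_correct, n_trials = res$n_trials,
                 fold_assignment = fold,
                 binomial_p = binomial_test(res$n_correct, res$n_trials),
                 weight_map = weight_map,
                 frequency_range_used = frange,
                 k_folds = k_folds, seed = seed,
                 standardize = standardize),
            class = "subject_decoding")
}

feature_matrix <- function(features, log_power = FALSE) {
  if (inherits(features, "spectral_features")) {
    d <- dim(features$power)
    # flatten channels x frequencies column-major (channel fastest)
    x <- matrix(features$power, d[1], d[2] * d[3])
    if (log_power) {
      if (any(x <= 0))
        stop("cannot log-transform non-positive power values")
      x <- log(x)
    }
    x
  } else as.matrix(features)
}

#' @export
print.subject_decoding <- function(x, ...) {
  cat(sprintf("<subject_decoding> accuracy %.3f (%d/%d), binomial p = %.2e\n",
              x$accuracy, x$n_correct, x$n_trials, x$binomial_p))
  if (!is.null(x$frequency_range_used))
    cat(sprintf("  frequency range %g-%g Hz, %d folds (seed %s)\n",
                x$frequency_range_used[1], x$frequency_range_used[2],
                x$k_folds, format(x$seed)))
  invisible(x)
}

#' Decode one subject, optionally restricted to a frequency range
#'
#' Convenience wrapper: [band_select()] (unless `frequency_range` is
#' `"full"`) followed by [svm_crossval()], recording the range used.
#'
#' @inheritParams svm_crossval
#' @param frequency_range `"full"`, a band name from [frequency_bands()],
#'   or an explicit length-2 Hz range.
#' @return A `subject_decoding` object.
#' @export
decode_subject <- function(features, labels, frequency_range = "full",
                           k_folds = 5, seed = 1,
                           standardize = c("per_fold", "global"),
                           log_power = TRUE) {
  stopifnot(inherits(features, "spectral_features"))
  restricted <- if (identical(frequency_range, "full")) features
                else band_select(features, frequency_range)
  out <- svm_crossval(restricted, labels, k_folds, seed,
                      match.arg(standardize), log_power)
  out$frequency_range_used <- range(restricted$freq_axis)
  out$frequency_range_name <- if (is.character(frequency_range))
    frequency_range else paste0(frequency_range, collapse = ":")
  out
}
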