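#' Tidy a subject decoding result
#'
#' Long-format view of the classifier weight map: one row per channel x
#' frequency cell, with the linear weight (positive favors the pain class).
#'
#' @param x A `subject_decoding` object.
#' @param ... Unused.
#' @return Tibble with columns `channel`, `frequency`, `weight`.
#' @method tidy subject_decoding
#' @export
tidy.subject_decoding <- function(x, ...) {
  w <- x$weight_map
  if (is.null(dim(w))) stop("no channel x frequency weight map available")
  tibble::tibble(channel = rep(rownames(w), ncol(w)),
                 frequency = rep(as.numeric(colnames(w)), each = nrow(w)),
                 weight = as.numeric(w))
}

#' @rdname tidy.subject_decoding
#' @method glance subject_decoding
#' @export
glance.subject_decoding <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_correct = x$n_correct,
                 n_trials = x$n_trials, binomial_p = x$binomial_p,
                 k_folds = x$k_folds,
                 fmin = x$frequency_range_used[1],
                 fmax = x$frequency_range_used[2])
}

#' Tidy a group result
#'
#' `tidy()` returns the per-subject, per-window, per-range decoding summary;
#' `glance()` a one-row tibble of the group-level statistics.
#'
#' @param x A `group_result` from [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy group_result
#' @export
tidy.group_result <- function(x, ...) x$decoding_summary

#' @rdname tidy.group_result
#' @method glance group_result
#' @export
glance.group_result <- function(x, ...) {
  tibble::tibble(
    group_accuracy = x$group_accuracy,
    left_accuracy = unname(x$per_site_accuracy["left"]),
    right_accuracy = unname(x$per_site_accuracy["right"]),
    null_mean = x$null_mean,
    permutation_p = x$permutation_p,
    n_significant = x$n_significant,
    n_subjects = x$n_subjects,
    anova_F = x$anova$F %||% NA_real_,
    anova_df2 = x$anova$df2 %||% NA_real_,
    anova_p = x$anova$p %||% NA_real_,
    accuracy_r = x$accuracy_correlation$r %||% NA_real_,
    accuracy_r_p = x$accuracy_correlation$p %||% NA_real_,
    power_r = x$power_correlation$r %||% NA_real_,
    power_r_p = x$power_correlation$p %||% NA_real_
  )
}

#' Plot a classifier weight map
#'
#' Channel x frequency heat map of the linear SVM weights; positive values
#' (red) favor the pain class.
#'
#' @param object A `subject_decoding` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subject_decoding
#' @export
autoplot.subject_decoding <- function(object, ...) {
  d <- tidy(object)
  d$channel <- factor(d$channel, levels = rev(rownames(object$weight_map)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$channel,
                                  fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "frequency (Hz)", y = NULL, fill = "weight",
                  title = sprintf("SVM weights (accuracy %.2f)",
                                  object$accuracy))
}

#' Plot the permutation null of the group accuracy
#'
#' Histogram of the permuted group-mean accuracies with the observed group
#' accuracy marked.
#'
#' @param object A `group_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot group_result
#' @export
autoplot.group_result <- function(object, ...) {
  d <- tibble::tibble(accuracy = object$null_distribution)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$group_accuracy,
                        colour = "red", linewidth = 1) +
    ggplot2::labs(x = "group mean accuracy (label-permutation null)",
                  y = "count",
                  title = sprintf("observed %.3f, p = %.4g",
                                  object$group_accuracy,
                                  object$permutation_p))
}

#' Plot the per-frequency pre/post power correlation
#'
#' Correlation of subject-mean pre- vs post-stimulus power per grid
#' frequency, with Bonferroni-significant frequencies highlighted.
#'
#' @param result A `group_result` (or the tibble from
#'   [per_frequency_correlation()]).
#' @return A ggplot object.
#' @export
plot_frequency_correlation <- function(result) {
  d <- if (inherits(result, "group_result")) result$per_frequency else result
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$r,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "frequency (Hz)", y = "pre/post correlation r",
                  fill = "Bonferroni\nsignificant")
}

#' @importFrom ggplot2 .data
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a
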