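# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @export
tidy.linear_scorer <- function(x, ...) {
  x$coefficients
}

#' @export
glance.linear_scorer <- function(x, ...) {
  tibble(family = x$family, n_features = nrow(x$coefficients),
         intercept = x$intercept, lambda = x$lambda)
}

#' @export
tidy.selection_result <- function(x, ...) {
  arrange(x$counts, desc(.data$count), .data$feature)
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble(n_candidates = x$n_candidates,
         n_accepted = sum(x$records$accepted),
         acceptance_rate = if (x$n_candidates > 0)
           sum(x$records$accepted) / x$n_candidates else NA_real_,
         n_robust = length(select_robust_features(x)))
}

#' @export
tidy.model_assessment <- function(x, ...) {
  if (!is.na(x$failure %||% NA)) {
    return(tibble(family = x$model_family, set = NA_character_))
  }
  bind_rows(mutate(x$train_report, set = "train"),
            mutate(x$test_report, set = "test")) |>
    mutate(family = x$model_family) |>
    select("family", "set", dplyr::everything())
}

#' @export
glance.model_assessment <- function(x, ...) {
  if (!is.na(x$failure %||% NA)) {
    return(tibble(family = x$model_family, success = FALSE,
                  failure = x$failure))
  }
  tibble(family = x$model_family,
         train_auc = x$train_report$auc, test_auc = x$test_report$auc,
         delong_p = x$delong_p, train_perm_p = x$train_rs_perm_p,
         test_perm_p = x$test_rs_perm_p, cutoff = x$cutoff,
         success = x$success, failure = NA_character_)
}

#' @export
tidy.clin_rad_model <- function(x, ...) {
  x$terms
}

#' @export
glance.clin_rad_model <- function(x, ...) {
  tibble(n_covariates = length(x$covariates),
         youden_cutoff = x$youden_cutoff,
         cutoff = x$cutoff,
         separation_fallback = x$separation)
}

#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: selection counts
#' (top features, count threshold line), ROC curves, decision curves and
#' calibration plots.
#'
#' @param object A result object.
#' @param top_n Number of features shown.
#' @param ... Unused.
#' @return A ggplot.
#' @name radscore-autoplot
NULL

#' @rdname radscore-autoplot
#' @export
autoplot.selection_result <- function(object, top_n = 20, ...) {
  d <- head(arrange(object$counts, desc(.data$count)), top_n)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$count), y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$config$min_count,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Times selected in accepted models",
                  title = "Feature selection counts") +
    ggplot2::theme_minimal()
}

#' @rdname radscore-autoplot
#' @export
autoplot.roc_points <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 1 - .data$specificity,
                                       y = .data$sensitivity)) +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "1 - Specificity", y = "Sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc[1])) +
    ggplot2::theme_minimal()
}

#' @rdname radscore-autoplot
#' @export
autoplot.dca_curve <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object),
                           c("net_benefit", "treat_all", "treat_none"),
                           names_to = "policy", values_to = "nb")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$nb,
                                  colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.1, NA)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  title = "Decision curve analysis") +
    ggplot2::theme_minimal()
}

#' @rdname radscore-autoplot
#' @param bins A tibble from [calibration_bins()].
#' @export
plot_calibration <- function(bins, ...) {
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mean_predicted,
                                     y = .data$observed_rate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point() + ggplot2::geom_line(colour = "steelblue") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability", y = "Observed rate",
                  title = "Calibration curve") +
    ggplot2::theme_minimal()
}
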