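#' Plot the two score densities and the balanced-error threshold
#'
#' @param object A `threshold_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_model <- function(object, ...) {
  df <- bind_rows(
    tibble(score = object$td$grid, density = object$td$density,
           cohort = "TD"),
    tibble(score = object$asd$grid, density = object$asd$density,
           cohort = "ASD")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$score, .data$density,
                                   colour = .data$cohort)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$h0, linetype = "dashed") +
    ggplot2::labs(
      x = "discriminant score", y = "density",
      title = sprintf("H0 = %.3f (Type I %.1f%%, Type II %.1f%%)",
                      object$h0, 100 * object$type1, 100 * object$type2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot pre/post score densities of a treated cohort
#'
#' @param object A `shift_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shift_report <- function(object, ...) {
  kde_pre <- fit_kde(object$pre_scores)
  kde_post <- fit_kde(object$post_scores)
  df <- bind_rows(
    tibble(score = kde_pre$grid, density = kde_pre$density,
           timepoint = "pre"),
    tibble(score = kde_post$grid, density = kde_post$density,
           timepoint = "post")
  )
  df$timepoint <- factor(df$timepoint, levels = c("pre", "post"))
  ggplot2::ggplot(df, ggplot2::aes(.data$score, .data$density,
                                   colour = .data$timepoint)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$h0, linetype = "dashed") +
    ggplot2::labs(
      x = "discriminant score", y = "density",
      title = sprintf("%s: Type II %.1f%% -> %.1f%%",
                      object$arm %||% "treatment arm",
                      100 * object$type2_pre, 100 * object$type2_post)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of measure appearance frequencies among top subsets
#'
#' @param object A `frequency_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frequency_report <- function(object, ...) {
  df <- as_tibble(object)
  df$measure <- factor(df$measure, levels = df$measure[order(df$pct)])
  ggplot2::ggplot(df, ggplot2::aes(.data$measure, .data$pct)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "% of qualifying models",
      title = sprintf("%d models at criterion >= %.3g",
                      attr(object, "n_qualifying"),
                      attr(object, "threshold"))
    ) +
    ggplot2::theme_minimal()
}

#' Observed versus cross-validated predictions for a regression
#'
#' @param object A `kpls_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kpls_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(.data$y, .data$y_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "observed change in VABS Composite",
      y = "cross-validated prediction",
      title = sprintf("LOO R^2 = %.3f", object$r2)
    ) +
    ggplot2::theme_minimal()
}

#' Best criterion value per subset size
#'
#' Line plot of the output of [best_by_size()].
#'
#' @param best A tibble with `k` and `best_value` columns.
#' @return A ggplot object.
#' @export
plot_best_by_size <- function(best) {
  ggplot2::ggplot(best, ggplot2::aes(.data$k, .data$best_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of measures", y = "best criterion value") +
    ggplot2::theme_minimal()
}
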