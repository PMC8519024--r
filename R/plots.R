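# ggplot2 displays for the main result types.

#' Plot a ridge solution path
#'
#' Coefficient profiles against `log10(lambda)` (the `Inf` sentinel is
#' dropped from the display; its coefficients are exactly zero).
#'
#' @param object A [ridge_path()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ridge_path
#' @export
autoplot.ridge_path <- function(object, ...) {
  df <- tidy(object)
  df <- df[is.finite(df$lambda), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = log10(.data$lambda), y = .data$estimate,
    group = .data$term, colour = .data$term
  )) +
    ggplot2::geom_line(show.legend = ncol(object$beta) <= 12) +
    ggplot2::labs(
      x = expression(log[10](lambda)), y = "coefficient",
      title = "Ridge solution path"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a confidence-region tuning profile
#'
#' Shows the globaltest statistic (or criterion value) along the penalty
#' grid with the critical value and the selected penalty marked.  Only
#' available when the tuning object stored its grid profile.
#'
#' @param object A `gt_tuning` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gt_tuning
#' @export
autoplot.gt_tuning <- function(object, ...) {
  if (is.null(object$profile)) {
    abort("this tuning result carries no grid profile to plot")
  }
  df <- object$profile
  df <- df[is.finite(df$lambda), , drop = FALSE]
  yvar <- setdiff(names(df), "lambda")[1]
  gp <- ggplot2::ggplot(df, ggplot2::aes(
    x = log10(.data$lambda), y = .data[[yvar]]
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(log[10](lambda)), y = yvar,
      title = sprintf("Tuning profile (%s)", object$method)
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$critical) && yvar == "statistic") {
    gp <- gp + ggplot2::geom_hline(yintercept = object$critical,
                                   linetype = "dashed")
  }
  if (is.finite(object$lambda)) {
    gp <- gp + ggplot2::geom_vline(xintercept = log10(object$lambda),
                                   linetype = "dotted")
  }
  gp
}

#' Plot null-model selection frequencies
#'
#' Dot-and-error-bar display of the output of [run_null_experiment()]:
#' per-method fraction of replications selecting `lambda = Inf`, with
#' 95% normal-approximation intervals.
#'
#' @param results Tibble from [run_null_experiment()].
#' @return A ggplot object.
#' @export
plot_null_frequencies <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(
    x = .data$method, y = .data$prop_null
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$prop_null - 1.96 * .data$se, 0),
                   ymax = pmin(.data$prop_null + 1.96 * .data$se, 1)),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "P(select null model)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
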