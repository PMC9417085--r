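#' Plot a scattering curve
#'
#' Log-log intensity plot with error bars.
#'
#' @param object A [sans_curve].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sans_curve <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$q, y = .data$i)
  ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$i - .data$di, ymax = .data$i + .data$di),
      width = 0, colour = "grey60"
    ) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(q ~ (ring(A)^{-1})),
      y = expression(I(q) ~ (cm^{-1})),
      title = attr(object, "contrast")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pair distance-distribution function
#'
#' @param object A `pddf` from [fit_pr()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pddf <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$r, y = .data$p)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$p - .data$dp, ymax = .data$p + .data$dp),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(
      x = expression(r ~ (ring(A))), y = "p(r)",
      subtitle = sprintf(
        "D_max = %.3g A, R_g = %.3g A", attr(object, "d_max"),
        attr(object, "rg")
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a multi-contrast co-refinement
#'
#' Data with error bars and fitted model per contrast, on shared
#' log-log axes.
#'
#' @param object A `sans_cofit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sans_cofit <- function(object, ...) {
  dat <- augment(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$q, colour = .data$contrast)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$i - .data$di, ymax = .data$i + .data$di),
      width = 0, alpha = 0.4
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$i), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$i_fit)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(q ~ (ring(A)^{-1})),
      y = expression(I(q) ~ (cm^{-1}))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an enthalpogram with detected transitions
#'
#' @param entha An [enthalpogram].
#' @param transitions Optional `itc_transitions` from
#'   [detect_transitions()]; boundaries drawn as dashed lines.
#' @return A ggplot.
#' @export
plot_enthalpogram <- function(entha, transitions = NULL) {
  p <- ggplot2::ggplot(
    as_tibble(entha),
    ggplot2::aes(x = .data$conc_mM, y = .data$heat)
  ) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "[SDS] in cell (mM)",
      y = "molar heat (kcal/mol injectant)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(transitions) && nrow(transitions$transitions)) {
    p <- p + ggplot2::geom_vline(
      data = transitions$transitions,
      ggplot2::aes(xintercept = .data$conc_mM),
      linetype = 2, colour = "firebrick"
    )
  }
  p
}

#' Plot a titration series with its breakpoint
#'
#' @param fit A `breakpoint_fit` from [breakpoint_intersection()].
#' @return A ggplot.
#' @export
plot_breakpoint <- function(fit) {
  dat <- fit$data
  seg <- tibble(
    intercept = c(fit$intercept_pre, fit$intercept_post),
    slope = c(fit$slope_pre, fit$slope_post)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = seg,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope),
      linetype = 2, colour = "grey40"
    ) +
    ggplot2::geom_vline(
      xintercept = fit$breakpoint, colour = "firebrick", linetype = 2
    ) +
    ggplot2::theme_minimal()
}
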