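#' Plot a reference-anchored causal curve
#'
#' Ribbon-and-line plot of the mean difference in grip strength (kg) by
#' 25(OH)D, with the reference point (difference 0) marked by a dot.
#'
#' @param object A `causal_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.causal_curve <- function(object, ...) {
  ref <- attr(object, "reference")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$difference)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower95, ymax = .data$upper95),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::annotate("point", x = ref, y = 0, size = 2) +
    ggplot2::labs(
      x = "Circulating 25(OH)D (nmol/L)",
      y = sprintf("Mean difference in grip strength vs %g nmol/L (kg)", ref)
    ) +
    ggplot2::theme_minimal()
}

#' Plot stratum LACE estimates with the fitted slope function
#'
#' Shows the localized average causal effect (kg per nmol/L) in each
#' doubly-ranked stratum against the stratum mean exposure, with 95%
#' intervals, overlaid with the fitted fractional-polynomial derivative.
#'
#' @param object An `nlmr_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nlmr_result <- function(object, ...) {
  strata <- tibble::as_tibble(object$strata)
  xs <- seq(min(strata$mean_x), max(strata$mean_x), length.out = 200)
  fitted <- tibble::tibble(
    x = xs,
    lace = as.numeric(fp_deriv_basis(xs, object$fit$powers) %*%
                        object$fit$coefficients)
  )
  ggplot2::ggplot(strata, ggplot2::aes(x = .data$mean_x, y = .data$lace)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$lace - 1.96 * .data$lace_se,
                   ymax = .data$lace + 1.96 * .data$lace_se),
      linewidth = 0.2, size = 0.2, alpha = 0.6
    ) +
    ggplot2::geom_line(data = fitted, ggplot2::aes(x = .data$x, y = .data$lace),
                       colour = "steelblue", linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(
      x = "Stratum mean 25(OH)D (nmol/L)",
      y = "LACE (kg per nmol/L)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.obs_result <- function(object, ...) {
  autoplot(object$curve) +
    ggplot2::ggtitle(sprintf("Observational dose-response (%s, n = %d)",
                             object$sex, object$n))
}
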