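#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Histogram of response deviations with optional fitted mixture
#'
#' Density-scaled histogram of wrapped response deviations, faceted by
#' coherence when present, with the fitted mixture density (and its
#' components) overlaid when a fit is supplied.
#'
#' @param data Tibble with a `deviation_deg` column (and optionally
#'   `coherence`), or a numeric vector.
#' @param fit Optional `vmmm_fit` overlaid as a density curve (only
#'   meaningful for un-faceted data).
#' @param binwidth Histogram bin width in degrees.
#' @return A ggplot object.
#' @export
plot_deviations <- function(data, fit = NULL, binwidth = 10) {
  if (!is.data.frame(data)) {
    data <- tibble::tibble(deviation_deg = as.numeric(data))
  }
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$deviation_deg)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(density)),
      binwidth = binwidth, boundary = -180,
      fill = "grey70", color = "grey40", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_x_continuous(limits = c(-180, 180),
                                breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = expression(Delta * theta ~ "(deg)"),
                  y = "density (per deg)") +
    ggplot2::theme_minimal()
  if ("coherence" %in% names(data) && length(unique(data$coherence)) > 1) {
    p <- p + ggplot2::facet_wrap(~coherence, labeller = ggplot2::label_both)
  }
  if (!is.null(fit)) {
    grid <- tibble::tibble(deviation_deg = seq(-180, 180, by = 0.5))
    grid$density <- mixture_pdf(grid$deviation_deg, fit$params, fit$model)
    p <- p + ggplot2::geom_line(
      data = grid, ggplot2::aes(y = .data$density), color = "#d95f02",
      linewidth = 0.8)
  }
  p
}

#' Plot a fitted mixture's components
#'
#' Shows the weighted detection, ROOD and guessing densities together with
#' the full mixture density.
#'
#' @param object A `vmmm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vmmm_fit <- function(object, ...) {
  theta <- seq(-180, 180, by = 0.5)
  p <- object$params
  spec <- model_spec(object$model)
  comp <- list(
    tibble::tibble(theta = theta, density = p$r3 / 360, component = "guess"))
  if (spec$use_det) {
    comp <- c(comp, list(tibble::tibble(
      theta = theta,
      density = p$r1 * von_mises_pdf(theta, p$mu, p$kappa1),
      component = "detection")))
  }
  if (spec$use_rood) {
    comp <- c(comp, list(tibble::tibble(
      theta = theta,
      density = p$r2 * von_mises_pdf(theta, p$mu + 180, p$kappa2),
      component = "rood")))
  }
  df <- dplyr::bind_rows(comp)
  mix <- tibble::tibble(theta = theta,
                        density = mixture_pdf(theta, p, object$model),
                        component = "mixture")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$theta, y = .data$density,
                                   color = .data$component)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_line(data = mix, linetype = "dashed", color = "black") +
    ggplot2::scale_x_continuous(breaks = seq(-180, 180, 90)) +
    ggplot2::labs(x = expression(Delta * theta ~ "(deg)"),
                  y = "density (per deg)",
                  title = sprintf("vMMM %s fit (n = %d)", object$model, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot Akaike weights of a model comparison
#'
#' @param object A `vmmm_comparison`.
#' @param ... Unused.
#' @return A ggplot bar chart of the four models' Akaike weights.
#' @export
autoplot.vmmm_comparison <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$model, y = .data$weight)) +
    ggplot2::geom_col(fill = "#1b9e77") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Akaike weight") +
    ggplot2::theme_minimal()
}

#' Group parameter curves over coherence
#'
#' Mean +/- SEM of each model-averaged parameter as a function of coherence,
#' as produced by [summarize_group()].
#'
#' @param summary Tibble from [summarize_group()].
#' @param parameters Parameters to show (default: the three mixture
#'   frequencies).
#' @return A ggplot object.
#' @export
plot_group_params <- function(summary, parameters = c("r1", "r2", "r3")) {
  df <- dplyr::filter(summary, .data$parameter %in% parameters)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coherence, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sem,
                                          ymax = .data$mean + .data$sem)) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "coherence", y = "group mean ± SEM") +
    ggplot2::theme_minimal()
}
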