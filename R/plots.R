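#' Plot the species productivity-biomass scaling
#'
#' Log-log scatter of species relative woody productivity against
#' period-mean biomass, optionally overlaid with a fitted power law.
#'
#' @param rates Population tibble from [species_rates()] (rows with
#'   `valid_p = FALSE` are dropped from the log axes).
#' @param fit Optional [fit_power_law()] object of `p` on `B` to overlay.
#' @param colour Optional column to colour points by (tidy-evaluated).
#' @return A ggplot object.
#' @export
plot_species_scaling <- function(rates, fit = NULL, colour = NULL) {
  d <- rates |> filter(.data$valid_p)
  gg <- ggplot2::ggplot(d, ggplot2::aes(.data$B, .data$p)) +
    ggplot2::geom_point(ggplot2::aes(colour = {{ colour }}),
                        alpha = 0.5, size = 1) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(B[i] ~ "(Mg C" ~ ha^-1 * ")"),
      y = expression(p[i] ~ "(" * yr^-1 * ")"),
      title = "Species relative woody productivity vs standing biomass"
    )
  if (!is.null(fit)) {
    xr <- exp(seq(log(min(d$B)), log(max(d$B)), length.out = 50))
    line <- tibble(B = xr, p = fit$a * xr^fit$b)
    gg <- gg + ggplot2::geom_line(data = line, colour = "black",
                                  linewidth = 0.8)
  }
  gg
}

#' Plot stand-level productivity-biomass scaling
#'
#' @param stands Tibble with `B`, `P` (e.g. from [stand_aggregate()] or
#'   [forest_totals()]) and optionally `forest`/`biome` for colour.
#' @return A ggplot object.
#' @export
plot_stand_scaling <- function(stands) {
  grp <- intersect(c("forest", "biome"), names(stands))
  aes <- if (length(grp)) {
    ggplot2::aes(.data$B, .data$P, colour = .data[[grp[1]]])
  } else {
    ggplot2::aes(.data$B, .data$P)
  }
  ggplot2::ggplot(stands, aes) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = expression(B ~ "(Mg C" ~ ha^-1 * ")"),
      y = expression(P ~ "(Mg C" ~ ha^-1 ~ yr^-1 * ")"),
      title = "Stand woody productivity vs stand biomass"
    )
}

#' Plot the stepwise species-removal curve
#'
#' Remaining plot productivity as the smallest-biomass species are removed
#' one at a time.
#'
#' @param curve Output of [stepwise_reduction_curve()].
#' @return A ggplot object.
#' @export
plot_stepwise_reduction <- function(curve) {
  ggplot2::ggplot(curve,
                  ggplot2::aes(.data$B_removed, .data$P_remaining,
                               group = .data$plot_id)) +
    ggplot2::geom_step(alpha = 0.7) +
    ggplot2::labs(
      x = expression("Cumulative removed species biomass (Mg C" ~ ha^-1 * ")"),
      y = expression("Remaining P (Mg C" ~ ha^-1 ~ yr^-1 * ")"),
      title = "Stepwise removal of small-biomass species"
    )
}

#' @describeIn fit_power_law Diagnostic plot: observations and fitted
#'   power law on log-log axes (pooled log-log fits only).
#' @param object A `power_law_fit`.
#' @method autoplot power_law_fit
#' @export
autoplot.power_law_fit <- function(object, ...) {
  mf <- object$lm$model
  if (!"lx" %in% names(mf)) {
    abort("autoplot.power_law_fit: only log-log fits can be plotted")
  }
  d <- tibble(x = exp(mf$lx), y = exp(mf$ly))
  xr <- exp(seq(min(mf$lx), max(mf$lx), length.out = 50))
  mat0 <- if ("mat" %in% names(mf)) mean(mf$mat) else NULL
  pred <- predict_at(object, x = xr, mat = mat0,
                     plot = if (!is.null(object$plot_intercepts))
                       object$plot_intercepts$plot_id[1])
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = pred,
                       ggplot2::aes(.data$x, .data$mean),
                       colour = "black") +
    ggplot2::geom_ribbon(data = pred,
                         ggplot2::aes(.data$x, ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "x", y = "y", title = paste("Power-law fit:", object$form))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
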