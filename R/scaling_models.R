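#' Fit a lognormal power-law scaling model
#'
#' Fits the log-linear model
#' \deqn{\ln y_j \sim \mathrm{Normal}(\mu_j, \sigma), \qquad
#'       \mu_j = k + b \ln x_j + c\,\mathrm{MAT}_j}
#' by ordinary least squares, equivalent on the natural scale to the
#' power law \eqn{y = a\,x^b \exp(c\,\mathrm{MAT})} with the lognormal
#' mean correction \eqn{a = \exp(k + \sigma^2/2)}. Any of the predictor
#' terms may be omitted; with `plot_intercepts = TRUE` a separate
#' intercept \eqn{k_{plot}} (hence \eqn{a_{plot}}) is fitted per plot as
#' fixed-effect dummies sharing a common slope.
#'
#' @param data A data frame of observations (species populations or plots).
#' @param y Response column (positive), tidy-evaluated.
#' @param x Optional positive predictor column entering as `ln x`.
#' @param mat Optional mean-annual-temperature column (degrees C),
#'   entering linearly.
#' @param plot Optional plot-identifier column, required when
#'   `plot_intercepts = TRUE`.
#' @param plot_intercepts Fit one intercept per plot instead of a pooled
#'   intercept.
#' @return An object of class `power_law_fit` with elements `k`, `b`, `c`,
#'   `sigma` (residual SD of `ln y`, denominator n - #coefficients), `a`,
#'   `se_k`, `se_b`, `se_c`, `r2` (on the log scale), `n`, `form`,
#'   `plot_intercepts` (tibble of per-plot `k` and `a` when fitted), and
#'   the underlying `lm` fit. Supports [tidy()], [glance()], [predict_at()]
#'   and [ggplot2::autoplot()].
#' @examples
#' d <- tibble::tibble(x = exp(seq(-2, 2, length.out = 20)), y = 2 * x^-0.15)
#' fit_power_law(d, y, x)
#' @export
fit_power_law <- function(data, y, x = NULL, mat = NULL, plot = NULL,
                          plot_intercepts = FALSE) {
  stopifnot(is.data.frame(data))
  yv <- eval_tidy(enquo(y), data)
  xq <- enquo(x); mq <- enquo(mat); pq <- enquo(plot)
  xv <- if (quo_is_null(xq)) NULL else eval_tidy(xq, data)
  mv <- if (quo_is_null(mq)) NULL else eval_tidy(mq, data)
  pv <- if (quo_is_null(pq)) NULL else eval_tidy(pq, data)
  if (any(!is.finite(yv) | yv <= 0)) {
    abort("fit_power_law: response must be positive and finite (filter first)")
  }
  if (!is.null(xv) && any(!is.finite(xv) | xv <= 0)) {
    abort("fit_power_law: x must be positive and finite")
  }
  if (plot_intercepts && is.null(pv)) {
    abort("fit_power_law: plot_intercepts = TRUE requires a plot column")
  }
  df <- tibble(ly = log(yv))
  terms <- character(0)
  if (plot_intercepts) {
    df$plot <- factor(pv)
    if (nlevels(df$plot) < 2) {
      abort("fit_power_law: plot-intercept form needs at least two plots (rank)")
    }
    terms <- c("0", "plot")
  }
  if (!is.null(xv)) { df$lx <- log(xv); terms <- c(terms, "lx") }
  if (!is.null(mv)) { df$mat <- mv; terms <- c(terms, "mat") }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fit <- lm(stats::as.formula(paste("ly ~", rhs)), data = df)
  if (any(is.na(coef(fit)))) {
    abort("fit_power_law: singular design (rank-deficient model matrix)")
  }
  n <- nrow(df)
  p_coef <- length(coef(fit))
  if (n <= p_coef) abort("fit_power_law: need more observations than coefficients")
  # noise-free inputs (exact recovery) are legitimate here; silence
  # summary.lm's perfect-fit warning but let anything else through
  quiet_perfect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  }
  sigma <- quiet_perfect(summary(fit)$sigma)
  cf <- coef(fit)
  se <- quiet_perfect(sqrt(diag(vcov(fit))))
  # r2 about the mean of ln y (summary() drops the mean for 0-intercept forms)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((df$ly - mean(df$ly))^2)
  b <- unname(cf["lx"]); se_b <- unname(se["lx"])
  cc <- unname(cf["mat"]); se_c <- unname(se["mat"])
  if (is.null(xv)) { b <- NA_real_; se_b <- NA_real_ }
  if (is.null(mv)) { cc <- 0; se_c <- NA_real_ }
  if (plot_intercepts) {
    pl <- grepl("^plot", names(cf))
    plot_tab <- tibble(
      plot_id = sub("^plot", "", names(cf)[pl]),
      k = unname(cf[pl]),
      se_k = unname(se[pl]),
      a = exp(unname(cf[pl]) + sigma^2 / 2)
    )
    k <- mean(plot_tab$k); se_k <- NA_real_
  } else {
    plot_tab <- NULL
    k <- unname(cf["(Intercept)"]); se_k <- unname(se["(Intercept)"])
  }
  structure(
    list(k = k, b = b, c = cc, sigma = sigma,
         a = lognormal_intercept(k, sigma),
         se_k = se_k, se_b = se_b, se_c = se_c,
         r2 = r2, n = n,
         form = paste0(if (is.null(xv)) "semi-log" else "log-log", " ",
                       if (plot_intercepts) "plot-intercepts" else "pooled"),
         plot_intercepts = plot_tab,
         x_range = if (is.null(xv)) NULL else range(xv),
         lm = fit),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat("Lognormal power-law fit (", x$form, "), n = ", x$n, "\n", sep = "")
  cat(sprintf("  k (log intercept) = %.4f%s\n", x$k,
              if (is.na(x$se_k)) " (mean over plots)" else
                sprintf(" (se %.4f)", x$se_k)))
  if (!is.na(x$b)) cat(sprintf("  b (exponent)      = %.4f (se %.4f)\n", x$b, x$se_b))
  if (x$c != 0 || !is.na(x$se_c)) {
    cat(sprintf("  c (MAT coef)      = %.4f (se %.4f)\n", x$c, x$se_c))
  }
  cat(sprintf("  sigma = %.4f;  a = exp(k + sigma^2/2) = %.4f;  R2 = %.4f\n",
              x$sigma, x$a, x$r2))
  invisible(x)
}

#' @rdname fit_power_law
#' @param x A `power_law_fit` object.
#' @param ... Unused.
#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  out <- tibble(
    term = c("k", "b", "c"),
    estimate = c(x$k, x$b, x$c),
    std.error = c(x$se_k, x$se_b, x$se_c)
  )
  fitted_terms <- c(TRUE, !is.na(x$b), !is.na(x$se_c))
  out[fitted_terms, ]
}

#' @rdname fit_power_law
#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble(r.squared = x$r2, sigma = x$sigma, a = x$a, nobs = x$n,
         form = x$form)
}

#' Lognormal mean correction of a power-law intercept
#'
#' Converts the log-scale intercept of a lognormal regression into the
#' natural-scale multiplicative constant, \eqn{a = \exp(k + \sigma^2/2)},
#' adjusting the mean of the lognormally distributed response.
#'
#' @param k Log-scale intercept.
#' @param sigma Residual SD of the log response (non-negative).
#' @return The natural-scale intercept `a`.
#' @export
lognormal_intercept <- function(k, sigma) {
  stopifnot(all(sigma >= 0))
  exp(k + sigma^2 / 2)
}

#' Predict from a power-law fit with confidence bounds
#'
#' Mean prediction \eqn{a\,x^b \exp(c\,\mathrm{MAT})} with Wald 95%
#' confidence bounds computed on the log scale from the coefficient
#' covariance (delta method) and exponentiated; the lognormal
#' \eqn{\sigma^2/2} correction is applied consistently to the mean and
#' both bounds, so at \eqn{\sigma = 0} the bounds are
#' \eqn{\exp(\hat\mu \pm 1.96\,\mathrm{se}(\hat\mu))}.
#'
#' @param fit A [fit_power_law()] object.
#' @param x Predictor value(s) on the natural scale (ignored for semi-log
#'   fits).
#' @param mat Mean annual temperature value(s), if the fit used MAT.
#' @param plot Plot id(s) for plot-intercept fits.
#' @param level Confidence level.
#' @return Tibble with `x`, `mat`, `mean`, `lower`, `upper`.
#' @export
predict_at <- function(fit, x = NULL, mat = NULL, plot = NULL, level = 0.95) {
  stopifnot(inherits(fit, "power_law_fit"))
  nd <- tibble(.rows = max(length(x), length(mat), length(plot), 1))
  if (!is.null(fit$x_range)) {
    if (is.null(x)) abort("predict_at: this fit needs x")
    if (any(x < fit$x_range[1] | x > fit$x_range[2])) {
      warn("predict_at: extrapolating beyond the observed x range")
    }
    nd$lx <- log(x)
  }
  if ("mat" %in% names(fit$lm$model)) {
    if (is.null(mat)) abort("predict_at: this fit needs mat")
    nd$mat <- mat
  }
  if (!is.null(fit$plot_intercepts)) {
    if (is.null(plot)) abort("predict_at: plot-intercept fit needs plot")
    nd$plot <- factor(plot, levels = levels(fit$lm$model$plot))
  }
  pr <- predict(fit$lm, newdata = nd, se.fit = TRUE)
  mu <- unname(pr$fit)
  se <- unname(pr$se.fit)
  z <- qnorm(1 - (1 - level) / 2)
  corr <- fit$sigma^2 / 2
  tibble(
    x = if (is.null(x)) NA_real_ else x,
    mat = if (is.null(mat)) NA_real_ else mat,
    mean = exp(mu + corr),
    lower = exp(mu - z * se + corr),
    upper = exp(mu + z * se + corr)
  )
}

#' Temperature span over which predicted productivity doubles
#'
#' For a MAT coefficient `c` (per degree C) of the power-law model, the
#' warming needed to double productivity at fixed biomass is
#' \eqn{\ln 2 / c}.
#'
#' @param c MAT coefficient, degrees C^-1 (positive).
#' @return Doubling span in degrees C; `NA` with a warning for `c <= 0`.
#' @examples
#' doubling_span(0.048) # ~14 C
#' @export
doubling_span <- function(c) {
  out <- log(2) / c
  if (any(c <= 0, na.rm = TRUE)) {
    warn("doubling_span: undefined for non-positive MAT coefficient")
    out[c <= 0] <- NA_real_
  }
  out
}

#' Classify forest biome from mean annual temperature
#'
#' Fixed MAT thresholds: tropical (MAT >= 24), subtropical (20-24),
#' warm-temperate (12-20), cool-temperate (5-12), sub-boreal (< 5 degrees C).
#' Boundaries belong to the warmer class.
#'
#' @param mat Mean annual temperature, degrees C.
#' @return Ordered factor of biome labels, coolest to warmest.
#' @export
classify_biome <- function(mat) {
  stopifnot(all(is.finite(mat)))
  cut(mat, breaks = c(-Inf, 5, 12, 20, 24, Inf), right = FALSE,
      labels = c("sub-boreal", "cool-temperate", "warm-temperate",
                 "subtropical", "tropical"),
      ordered_result = TRUE)
}

#' Linearity of inverse absolute temperature in MAT
#'
#' Metabolic theory writes temperature dependence against
#' \eqn{1/(273.15 + \mathrm{MAT})}; over a narrow MAT range this is almost
#' exactly linear in MAT, which justifies using MAT directly in the model.
#' Returns the R-squared of regressing \eqn{1/(273.15+\mathrm{MAT})} on MAT
#' over an evenly spaced grid.
#'
#' @param mat_min,mat_max Grid range, degrees C.
#' @param n_points Grid size (>= 3).
#' @return R-squared of the linear fit.
#' @examples
#' inverse_temperature_linearity(0, 30) # ~0.999
#' @export
inverse_temperature_linearity <- function(mat_min = 0, mat_max = 30,
                                          n_points = 31) {
  stopifnot(mat_min < mat_max, n_points >= 3)
  mat <- seq(mat_min, mat_max, length.out = n_points)
  invT <- 1 / (273.15 + mat)
  summary(lm(invT ~ mat))$r.squared
}
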