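#' Species-response projection of plot productivity
#'
#' Projects each plot's woody productivity under the species-response
#' hypothesis: every species everywhere obeys its plot's fitted power law
#' \eqn{p_i = a_{plot} B_i^{b}}, while all plots share one common frequency
#' distribution of species biomass — that of all named populations pooled
#' across plots. The projection is
#' \deqn{P_{specRes} = a_{plot}\, B\,
#'   \Big(\sum_{plot}\sum_i B_i^{1+b}\Big) \Big/ \sum_{plot} B,}
#' where the double sum and the biomass totals \eqn{B} run over named
#' (non-aggregate) populations, and each plot's pooled rare-species
#' aggregate contributes its own observed \eqn{P_i} unchanged. The formula
#' implicitly assumes plot species richness proportional to plot biomass.
#'
#' @param rates Population tibble from [species_rates()] (all plots).
#' @param b Common power-law exponent from a plot-intercept fit.
#' @param a_plot Data frame with `plot_id`, `a` — per-plot natural-scale
#'   intercepts, e.g. `fit$plot_intercepts` from [fit_power_law()].
#' @return Tibble `plot_id`, `P_specRes`.
#' @export
species_response_projection <- function(rates, b, a_plot) {
  stopifnot(is.data.frame(rates), is.numeric(b), length(b) == 1,
            is.data.frame(a_plot), all(c("plot_id", "a") %in% names(a_plot)))
  named <- rates |> filter(!.data$is_aggregate, is.finite(.data$B))
  ratio <- sum(named$B^(1 + b)) / sum(named$B)
  agg <- rates |>
    filter(.data$is_aggregate) |>
    group_by(.data$plot_id) |>
    summarise(P_agg = sum(.data$P, na.rm = TRUE), .groups = "drop")
  out <- named |>
    group_by(.data$plot_id) |>
    summarise(B_named = sum(.data$B), .groups = "drop") |>
    left_join(a_plot[, c("plot_id", "a")], by = "plot_id") |>
    left_join(agg, by = "plot_id")
  if (anyNA(out$a)) {
    abort(paste0("species_response_projection: no a_plot for plot(s) ",
                 paste(out$plot_id[is.na(out$a)], collapse = ", ")))
  }
  out |>
    mutate(P_specRes = .data$a * .data$B_named * ratio +
             dplyr::coalesce(.data$P_agg, 0)) |>
    select("plot_id", "P_specRes")
}

#' Replace species productivities by biomass-similarity resampling
#'
#' Implements the community-structure "replaced data": each named species
#' population's absolute productivity \eqn{P_i} is replaced by the mean of
#' `n_draws` weighted draws (with replacement) from the pool of all other
#' named populations across all plots, with weights
#' \eqn{w_j = 1/(\ln B_j - \ln B_i)^2} — so donors of similar standing
#' biomass dominate. Aggregate rare-species populations are excluded from
#' the pool and left unchanged.
#'
#' Exact log-biomass ties would give infinite weight; candidates within
#' `tie_tol` of the target in `ln B` are instead sampled uniformly among
#' themselves, the limit of the stated weight.
#'
#' @param rates Population tibble from [species_rates()] (all plots).
#' @param n_draws Number of resampling draws per population.
#' @param seed Integer seed; draws are reproducible given the seed and do
#'   not disturb the caller's random-number state.
#' @param deterministic If `TRUE`, skip sampling and return the closed-form
#'   weighted expectation \eqn{\sum_j w_j P_j / \sum_j w_j} (the
#'   infinite-draw limit); used for exact tests.
#' @param tie_tol Log-biomass tie tolerance.
#' @return The input tibble with a `P_replaced` column (`NA` for
#'   aggregates and populations with undefined `B` or `P`).
#' @export
replace_productivity <- function(rates, n_draws = 10000, seed = NULL,
                                 deterministic = FALSE, tie_tol = 1e-9) {
  stopifnot(is.data.frame(rates), n_draws >= 1)
  rates <- as_tibble(rates)
  eligible <- !rates$is_aggregate & is.finite(rates$B) & rates$B > 0 &
    is.finite(rates$P)
  if (sum(eligible) < 2) {
    abort("replace_productivity: need at least two eligible populations")
  }
  lnB <- log(rates$B)
  Pv <- rates$P
  idx <- which(eligible)
  one_target <- function(i) {
    pool <- setdiff(idx, i)
    d <- lnB[pool] - lnB[i]
    tied <- abs(d) < tie_tol
    if (any(tied)) {
      w <- as.numeric(tied)
    } else {
      w <- 1 / d^2
    }
    if (deterministic) {
      sum(w * Pv[pool]) / sum(w)
    } else {
      mean(sample(Pv[pool], n_draws, replace = TRUE, prob = w))
    }
  }
  run <- function() vapply(idx, one_target, numeric(1))
  vals <- if (deterministic || is.null(seed)) run() else
    withr::with_seed(seed, run())
  rates$P_replaced <- NA_real_
  rates$P_replaced[idx] <- vals
  rates
}

#' Community-structure projection of plot productivity
#'
#' Sums the replaced species productivities per plot, adding each plot's
#' aggregate rare-species productivity unchanged:
#' \eqn{P_{commStr} = \sum_i P_i^{replaced} + P_{aggregate}}.
#'
#' @param replaced Output of [replace_productivity()].
#' @return Tibble `plot_id`, `P_commStr`.
#' @export
community_structure_projection <- function(replaced) {
  stopifnot(is.data.frame(replaced), "P_replaced" %in% names(replaced))
  replaced |>
    group_by(.data$plot_id) |>
    summarise(
      P_commStr = sum(.data$P_replaced[!.data$is_aggregate], na.rm = TRUE) +
        sum(.data$P[.data$is_aggregate], na.rm = TRUE),
      .groups = "drop"
    )
}

#' Contribution ratio of a null-model projection
#'
#' Quantifies how much of the explained variance in observed log
#' productivity a null-model projection reproduces. The observed model
#' regresses \eqn{\ln P} on \eqn{(\ln B, \mathrm{MAT})}; the null series is
#' either re-fitted with the same model form and its fitted surface used to
#' predict \eqn{\ln P} (`method = "refit"`, default) or used directly as
#' the prediction (`method = "direct"`). The ratio is
#' \deqn{\frac{\mathrm{Var}(\ln P) - \mathrm{RSS}_{null}/n}
#'            {\mathrm{Var}(\ln P) - \mathrm{RSS}_{orig}/n},}
#' 1 when the null projection explains \eqn{\ln P} as completely as the
#' observed-data model, 0 when it explains nothing.
#'
#' @param plots Plot-level tibble with columns `P`, `B`, and `mat_c`
#'   (observed productivity, biomass, temperature), plus the null column.
#' @param null Tidy-evaluated column of null-projected productivity
#'   (natural scale), e.g. `P_specRes` or `P_commStr`.
#' @param method `"refit"` or `"direct"` (see above).
#' @return The contribution ratio (scalar); `NA` with a warning when the
#'   observed model itself explains nothing.
#' @export
contribution_ratio <- function(plots, null, method = c("refit", "direct")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(plots),
            all(c("P", "B", "mat_c") %in% names(plots)))
  nv <- eval_tidy(enquo(null), plots)
  lnP <- log(plots$P)
  lnB <- log(plots$B)
  mat <- plots$mat_c
  n <- length(lnP)
  rss <- function(pred) sum((lnP - pred)^2)
  fit_orig <- lm(lnP ~ lnB + mat)
  pred_null <- if (method == "refit") {
    stats::fitted(lm(log(nv) ~ lnB + mat))
  } else {
    log(nv)
  }
  v <- sum((lnP - mean(lnP))^2) / n
  denom <- v - rss(stats::fitted(fit_orig)) / n
  if (denom <= 0) {
    warn("contribution_ratio: observed model explains nothing; ratio undefined")
    return(NA_real_)
  }
  (v - rss(pred_null) / n) / denom
}
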