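#' Instantaneous relative woody productivity
#'
#' The instantaneous estimator of a population's relative aboveground woody
#' productivity over a census interval,
#' \deqn{p = \ln(B_T / B\mathrm{surv}_0) / T,}
#' where \eqn{B_T} is final biomass and \eqn{B\mathrm{surv}_0} the initial
#' biomass of trees that survived the interval. For survivors growing
#' exponentially at rate \eqn{g} with recruits entering, \eqn{p} recovers
#' \eqn{g} plus the ingrowth contribution. May legitimately be non-positive
#' (diameter shrinkage); values are flagged downstream, not erased.
#'
#' @param BT Final per-area biomass, Mg C ha^-1.
#' @param Bsurv0 Surviving fraction of initial biomass, Mg C ha^-1.
#' @param T_years Census interval, yr.
#' @return Relative productivity, yr^-1; `NA` where `Bsurv0` is zero or
#'   non-finite (undefined rate).
#' @export
relative_productivity <- function(BT, Bsurv0, T_years) {
  stopifnot(all(T_years > 0, na.rm = TRUE))
  out <- log(BT / Bsurv0) / T_years
  out[!is.finite(Bsurv0) | Bsurv0 <= 0 | !is.finite(BT) | BT <= 0] <- NA_real_
  out
}

#' Instantaneous relative woody loss rate
#'
#' Relative rate of aboveground biomass loss to tree mortality,
#' \deqn{l = \ln(B_0 / B\mathrm{surv}_0) / T \ge 0,}
#' zero exactly when no biomass died.
#'
#' @param B0 Initial per-area biomass, Mg C ha^-1.
#' @inheritParams relative_productivity
#' @return Relative loss, yr^-1; `NA` where undefined.
#' @export
relative_loss <- function(B0, Bsurv0, T_years) {
  stopifnot(all(T_years > 0, na.rm = TRUE))
  out <- log(B0 / Bsurv0) / T_years
  out[!is.finite(Bsurv0) | Bsurv0 <= 0 | !is.finite(B0) | B0 <= 0] <- NA_real_
  out
}

#' Period-mean biomass (logarithmic mean)
#'
#' The period-mean of an exponentially changing stock over two censuses,
#' \deqn{B = (B_T - B_0) / \ln(B_T / B_0),}
#' the logarithmic mean of the two census biomasses: symmetric in its
#' arguments, bounded between them, and never above their arithmetic mean.
#' When the two values agree to within a relative log-difference `guard`,
#' the arithmetic mean is returned (the second-order-accurate continuation
#' of the log-mean at its removable singularity).
#'
#' @param B0,BT Census biomasses, Mg C ha^-1 (both positive).
#' @param guard Log-ratio threshold below which the arithmetic mean is used.
#' @return Period-mean biomass; `NA` where either argument is non-positive.
#' @export
period_mean_biomass <- function(B0, BT, guard = 1e-9) {
  log_mean(B0, BT, guard = guard)
}

#' Period-mean stem abundance
#'
#' Logarithmic mean of the two census stem counts, with an arithmetic-mean
#' fallback (and a warning) when exactly one count is zero, and zero when
#' both are.
#'
#' @param N0,NT Per-area stem counts at the two censuses, ha^-1.
#' @inheritParams period_mean_biomass
#' @return Period-mean abundance, ha^-1.
#' @export
period_mean_abundance <- function(N0, NT, guard = 1e-9) {
  out <- log_mean(N0, NT, guard = guard)
  one_zero <- xor(N0 <= 0, NT <= 0)
  if (any(one_zero, na.rm = TRUE)) {
    warn("period_mean_abundance: zero count at one census; using arithmetic mean")
    out[one_zero] <- (N0[one_zero] + NT[one_zero]) / 2
  }
  out[N0 <= 0 & NT <= 0] <- 0
  out
}

#' Compute demographic rates for species populations
#'
#' The core per-population verb: adds instantaneous relative productivity
#' `p` and loss `l`, period-mean biomass `B` and abundance `N`, absolute
#' productivity `P = p B` and loss `L = l B`, the per-population simple
#' estimate `P_simple`, and a `valid_p` flag (`FALSE` for non-positive or
#' undefined `p`, and for the aggregate population) marking rows eligible
#' for productivity-biomass model fitting.
#'
#' Populations with `Bsurv0 = 0` (possible only for the pooled aggregate)
#' have undefined rates: they contribute their period-mean biomass to plot
#' totals but nothing to `P` or `L`, and are reported via a message.
#'
#' @param populations Tibble from [build_populations()] /
#'   [aggregate_rare_species()].
#' @param recruit_threshold_mass Carbon mass (Mg C) assigned as the initial
#'   mass of each recruited tree in the simple estimate, e.g. from
#'   [threshold_mass()]. `NULL` counts recruits at their full final mass —
#'   the only option when tree-level detail is gone.
#' @param guard Log-mean singularity guard passed to
#'   [period_mean_biomass()].
#' @return The input tibble with columns `p`, `l`, `B`, `N`, `P`, `L`,
#'   `P_simple`, `valid_p` appended.
#' @examples
#' pops <- tibble::tibble(plot_id = "p1", species = "sp1",
#'   B0 = 100, BT = 110, Bsurv0 = 95, T = 5, n_surv = 10, n_recruit = 0,
#'   N0 = 12, NT = 12, Wmax = 2, is_aggregate = FALSE)
#' species_rates(pops)
#' @export
species_rates <- function(populations, recruit_threshold_mass = NULL,
                          guard = 1e-9) {
  stopifnot(is.data.frame(populations))
  pops <- as_tibble(populations)
  undef <- pops$Bsurv0 <= 0
  if (any(undef)) {
    inform(paste0("species_rates: ", sum(undef),
                  " population(s) with no surviving biomass; ",
                  "rates undefined, biomass retained in plot totals"))
  }
  # recruit convention for the simple estimate: deduct the threshold-size
  # mass per recruit (per-area count, so units match the biomasses)
  nrec <- pops$n_recruit_ha %||% pops$n_recruit
  deduct <- if (is.null(recruit_threshold_mass)) 0 else
    recruit_threshold_mass * nrec
  pops |>
    mutate(
      p = relative_productivity(.data$BT, .data$Bsurv0, .data$T),
      l = relative_loss(.data$B0, .data$Bsurv0, .data$T),
      B = period_mean_biomass(.data$B0, .data$BT, guard = guard),
      N = period_mean_abundance(.data$N0, .data$NT, guard = guard),
      P = .data$p * .data$B,
      L = .data$l * .data$B,
      P_simple = (.data$BT - .data$Bsurv0 - deduct) / .data$T,
      valid_p = !.data$is_aggregate & is.finite(.data$p) & .data$p > 0
    )
}

#' Aggregate populations to forest-plot totals
#'
#' Sums species populations to stand level: period-mean biomass
#' \eqn{B = \sum_i B_i}, woody productivity \eqn{P = \sum_i p_i B_i}, loss
#' \eqn{L = \sum_i l_i B_i}, the conventional simple estimate
#' `P_simple`, and species richness `SR` (distinct named species codes;
#' the pooled aggregate is one population but not one species). Populations
#' with non-positive `p` are included — only model fitting excludes them.
#'
#' @param rates Tibble from [species_rates()].
#' @param plot_meta Optional plot metadata ([read_plot_metadata()]); joins
#'   `mat_c`, `biome`, and (when a `litter_fall` column is present,
#'   Mg C ha^-1 yr^-1) computes `ANPP = P + litter_fall`.
#' @return One row per plot: `plot_id`, `B`, `P`, `L`, `P_simple`, `SR`,
#'   plus joined metadata columns.
#' @export
forest_totals <- function(rates, plot_meta = NULL) {
  stopifnot(is.data.frame(rates))
  out <- rates |>
    group_by(.data$plot_id) |>
    summarise(
      B = sum(.data$B, na.rm = TRUE),
      P = sum(.data$P, na.rm = TRUE),
      L = sum(.data$L, na.rm = TRUE),
      P_simple = sum(.data$P_simple, na.rm = TRUE),
      SR = dplyr::n_distinct(.data$species[!.data$is_aggregate]),
      .groups = "drop"
    )
  if (!is.null(plot_meta)) {
    out <- left_join(out, as_tibble(plot_meta), by = "plot_id")
    if ("litter_fall" %in% names(out)) {
      out$ANPP <- anpp(out$P, out$litter_fall)
    }
  }
  out
}

#' Conventional simple productivity estimate
#'
#' The standard interval estimate of woody productivity,
#' \deqn{P_{simple} = \sum_i (B_{Ti} - B\mathrm{surv}_{0i}) / T,}
#' with recruited trees entering at the threshold-size mass when that
#' convention can be applied. Biased low relative to the instantaneous
#' estimator when turnover is appreciable over the interval.
#'
#' @inheritParams species_rates
#' @return The populations tibble with a `P_simple` column.
#' @export
simple_productivity <- function(populations, recruit_threshold_mass = NULL) {
  stopifnot(is.data.frame(populations))
  nrec <- populations$n_recruit_ha %||% populations$n_recruit
  deduct <- if (is.null(recruit_threshold_mass)) 0 else
    recruit_threshold_mass * nrec
  populations |>
    mutate(P_simple = (.data$BT - .data$Bsurv0 - deduct) / .data$T)
}

#' Select populations eligible for productivity-biomass model fitting
#'
#' Drops the pooled aggregate populations and any population with
#' non-positive or undefined relative productivity, and reports how many
#' were excluded (attribute `"excluded"`: a one-row tibble of counts).
#'
#' @param rates Tibble from [species_rates()].
#' @return Filtered tibble with attribute `"excluded"`.
#' @export
filter_for_fitting <- function(rates) {
  stopifnot(is.data.frame(rates))
  keep <- rates |> filter(.data$valid_p)
  n_agg <- sum(rates$is_aggregate)
  n_named <- sum(!rates$is_aggregate)
  n_nonpos <- n_named - nrow(keep)
  inform(paste0("filter_for_fitting: kept ", nrow(keep), " of ", n_named,
                " named populations (", n_nonpos,
                " with non-positive/undefined p excluded; ", n_agg,
                " aggregate(s) excluded)"))
  attr(keep, "excluded") <- tibble(
    n_named = n_named, n_excluded_nonpositive = n_nonpos,
    n_aggregate = n_agg,
    fraction_excluded = if (n_named > 0) n_nonpos / n_named else NA_real_
  )
  keep
}

#' Stepwise small-to-large species removal curve
#'
#' For each plot, orders species populations by ascending period-mean
#' biomass and removes them one at a time, tracking the remaining plot
#' productivity: how much of `P` survives if the smallest-biomass species
#' are deleted. The first row is the intact plot; the last row is the
#' largest-biomass population alone.
#'
#' @param rates Tibble from [species_rates()].
#' @return Tibble with `plot_id`, `n_removed`, `B_removed` (cumulative
#'   biomass of removed species), `P_remaining`.
#' @export
stepwise_reduction_curve <- function(rates) {
  stopifnot(is.data.frame(rates))
  rates |>
    group_by(.data$plot_id) |>
    arrange(.data$B, .by_group = TRUE) |>
    dplyr::reframe(
      n_removed = seq_len(n()) - 1L,
      B_removed = cumsum(dplyr::lag(.data$B, default = 0)),
      P_remaining = sum(.data$P, na.rm = TRUE) -
        cumsum(dplyr::lag(dplyr::coalesce(.data$P, 0), default = 0))
    )
}

#' Productivity share of small-biomass species
#'
#' Fraction of plot woody productivity contributed by species whose
#' period-mean biomass falls below a threshold (3 Mg C ha^-1 by default) —
#' the "small-biomass species" share.
#'
#' @param rates Tibble from [species_rates()].
#' @param threshold Biomass threshold, Mg C ha^-1.
#' @return Tibble `plot_id`, `small_biomass_fraction`; `NA` with a warning
#'   where plot `P` is zero.
#' @export
small_biomass_contribution <- function(rates, threshold = 3) {
  stopifnot(is.data.frame(rates))
  out <- rates |>
    group_by(.data$plot_id) |>
    summarise(
      small_biomass_fraction = {
        ptot <- sum(.data$P, na.rm = TRUE)
        if (!is.finite(ptot) || ptot == 0) NA_real_ else
          sum(.data$P[.data$B < threshold], na.rm = TRUE) / ptot
      },
      .groups = "drop"
    )
  if (anyNA(out$small_biomass_fraction)) {
    warn("small_biomass_contribution: undefined for plot(s) with zero P")
  }
  out
}

#' Aboveground net primary productivity
#'
#' Woody productivity plus fine litter fall over the same period. Use
#' [annual_litter()] first if litter is recorded as monthly sums.
#'
#' @param P Woody productivity, Mg C ha^-1 yr^-1.
#' @param litter_fall Annual fine litter fall, Mg C ha^-1 yr^-1.
#' @return ANPP, Mg C ha^-1 yr^-1.
#' @export
anpp <- function(P, litter_fall) {
  stopifnot(all(P >= 0 | is.na(P)), all(litter_fall >= 0 | is.na(litter_fall)))
  P + litter_fall
}

#' Sum a monthly litter-fall series to an annual rate
#'
#' @param monthly Numeric vector of monthly litter-fall sums
#'   (Mg C ha^-1 month^-1) covering whole years.
#' @return Annual litter fall, Mg C ha^-1 yr^-1.
#' @export
annual_litter <- function(monthly) {
  stopifnot(length(monthly) %% 12 == 0)
  sum(monthly) / (length(monthly) / 12)
}
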