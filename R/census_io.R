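#' Read and validate a two-census tree table
#'
#' Reads a census CSV (one row per stem recorded in either of two censuses)
#' and validates it against the estimator's input contract: a positive
#' inter-census interval, consistent alive flags, and the minimum census
#' diameter (trees must reach `min_diameter_cm` in at least one census).
#' Rows failing validation are dropped and reported, with their row numbers,
#' in the `"rejected"` attribute of the returned tibble.
#'
#' Either a `T_years` column or a pair of ISO-8601 `date1`/`date2` columns
#' must be present; dates are converted to a decimal-year interval as the
#' day difference divided by 365.25.
#'
#' @param path Path to the census CSV (UTF-8, comma-separated, header).
#' @param schema Named character vector mapping canonical column names
#'   (`plot_id`, `tree_id`, `species`, `d1_cm`, `d2_cm`, `alive1`, `alive2`,
#'   `T_years`, `date1`, `date2`, `w1`, `w2`) to the file's column names.
#'   Unmapped names are looked up verbatim.
#' @param min_diameter_cm Census diameter threshold, cm; rows below it at
#'   both censuses are rejected, not silently dropped.
#' @return A tibble of validated tree records with attribute `"rejected"`
#'   (tibble of `row`, `reason`).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("plot_id,tree_id,species,d1_cm,d2_cm,alive1,alive2,T_years",
#'              "p1,t1,sp1,10,12,TRUE,TRUE,5"), f)
#' read_census_table(f)
#' @export
read_census_table <- function(path, schema = NULL, min_diameter_cm = 5) {
  if (!file.exists(path)) abort(paste0("census file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  canon <- c("plot_id", "tree_id", "species", "d1_cm", "d2_cm",
             "alive1", "alive2", "T_years", "date1", "date2", "w1", "w2")
  for (nm in canon) {
    src <- if (!is.null(schema) && nm %in% names(schema)) schema[[nm]] else nm
    if (src %in% names(raw) && src != nm) names(raw)[names(raw) == src] <- nm
  }
  required <- c("plot_id", "tree_id", "species", "alive1", "alive2")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort(paste0("census schema error: missing column(s) ",
                 paste(miss, collapse = ", ")))
  }
  has_mass <- all(c("w1", "w2") %in% names(raw))
  if (!has_mass && !all(c("d1_cm", "d2_cm") %in% names(raw))) {
    abort("census schema error: need d1_cm/d2_cm (or w1/w2) columns")
  }
  if (!"T_years" %in% names(raw)) {
    if (!all(c("date1", "date2") %in% names(raw))) {
      abort("census schema error: need T_years or date1/date2 columns")
    }
    d1 <- as.Date(raw$date1)
    d2 <- as.Date(raw$date2)
    raw$T_years <- as.numeric(d2 - d1) / 365.25
  }
  raw$alive1 <- as.logical(raw$alive1)
  raw$alive2 <- as.logical(raw$alive2)
  for (nm in intersect(c("d1_cm", "d2_cm", "w1", "w2", "T_years"), names(raw))) {
    raw[[nm]] <- as.numeric(raw[[nm]])
  }

  reason <- rep(NA_character_, nrow(raw))
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reason[is.na(reason) & bad] <<- why
  }
  flag(!is.finite(raw$T_years) | raw$T_years <= 0,
       "non-positive or missing census interval")
  flag(!raw$alive1 & !raw$alive2, "not alive at either census")
  if (!has_mass) {
    d1 <- ifelse(raw$alive1, raw$d1_cm, NA_real_)
    d2 <- ifelse(raw$alive2, raw$d2_cm, NA_real_)
    flag(raw$alive1 & !is.finite(raw$d1_cm), "alive at census 1 without diameter")
    flag(raw$alive2 & !is.finite(raw$d2_cm), "alive at census 2 without diameter")
    below <- function(d) !is.na(d) & d < min_diameter_cm
    under1 <- !raw$alive1 | below(d1)
    under2 <- !raw$alive2 | below(d2)
    flag(under1 & under2, paste0("below ", min_diameter_cm,
                                 " cm threshold at both censuses"))
  } else {
    flag(raw$alive1 & (!is.finite(raw$w1) | raw$w1 < 0),
         "alive at census 1 without non-negative mass")
    flag(raw$alive2 & (!is.finite(raw$w2) | raw$w2 < 0),
         "alive at census 2 without non-negative mass")
  }
  rejected <- tibble(row = which(!is.na(reason)),
                     reason = reason[!is.na(reason)])
  if (nrow(rejected)) {
    inform(paste0("read_census_table: rejected ", nrow(rejected), " of ",
                  nrow(raw), " rows (see attr(., 'rejected'))"))
  }
  out <- raw[is.na(reason), , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Read per-plot metadata
#'
#' Plot metadata CSV with columns `plot_id`, `area_ha`, `mat_c` and optional
#' `ap_mm`, `biome`, `litter_fall`. A missing `biome` column is derived from
#' mean annual temperature via [classify_biome()].
#'
#' @param path Path to the metadata CSV.
#' @return A tibble, one row per plot.
#' @export
read_plot_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("plot metadata file not found: ", path))
  meta <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("plot_id", "area_ha", "mat_c")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(paste0("plot metadata: missing column(s) ",
                 paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(meta$area_ha) | meta$area_ha <= 0)) {
    abort("plot metadata: area_ha must be positive")
  }
  if (!"biome" %in% names(meta)) meta$biome <- classify_biome(meta$mat_c)
  as_tibble(meta)
}

#' Assemble species populations from tree records
#'
#' Collapses validated tree records into per-plot, per-species census sums:
#' initial and final per-area biomass (`B0`, `BT`, Mg C ha^-1), the surviving
#' fraction of initial biomass (`Bsurv0`), stem counts (`N0`, `NT`, ha^-1),
#' survivor counts, recruit bookkeeping, and the maximum individual tree mass
#' observed for the species over both censuses (`Wmax`, Mg C).
#'
#' All trees in a plot are assumed to share one census interval; per-tree
#' `T_years` variation is collapsed to the plot mean with a warning.
#'
#' @param records Tree-record tibble with masses filled (`w1`, `w2`), e.g.
#'   from [read_census_table()] + [apply_allometry()].
#' @param plot_area Either a single plot area (ha) or a data frame with
#'   `plot_id`, `area_ha`.
#' @return A tibble with one row per (plot, species) population, columns
#'   `plot_id`, `species`, `B0`, `BT`, `Bsurv0`, `T`, `n_surv`, `n_recruit`,
#'   `N0`, `NT`, `Wmax`, `is_aggregate` (all `FALSE` here; see
#'   [aggregate_rare_species()]).
#' @export
build_populations <- function(records, plot_area = 1) {
  stopifnot(is.data.frame(records))
  need <- c("plot_id", "species", "alive1", "alive2", "w1", "w2", "T_years")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    abort(paste0("build_populations: missing column(s) ",
                 paste(miss, collapse = ", ")))
  }
  if (is.data.frame(plot_area)) {
    areas <- plot_area[, c("plot_id", "area_ha")]
  } else {
    stopifnot(is.numeric(plot_area), length(plot_area) == 1)
    areas <- tibble(plot_id = unique(records$plot_id), area_ha = plot_area)
  }
  if (any(!is.finite(areas$area_ha) | areas$area_ha <= 0)) {
    abort("build_populations: plot area must be positive")
  }
  tspread <- records |>
    group_by(.data$plot_id) |>
    summarise(T = mean(.data$T_years),
              spread = diff(range(.data$T_years)), .groups = "drop")
  if (any(tspread$spread > 1e-8)) {
    warn("heterogeneous census intervals within plot(s); collapsed to the plot mean")
  }
  records |>
    left_join(areas, by = "plot_id") |>
    left_join(tspread[, c("plot_id", "T")], by = "plot_id") |>
    group_by(.data$plot_id, .data$species) |>
    summarise(
      B0 = sum(.data$w1[.data$alive1]) / .data$area_ha[1],
      BT = sum(.data$w2[.data$alive2]) / .data$area_ha[1],
      Bsurv0 = sum(.data$w1[.data$alive1 & .data$alive2]) / .data$area_ha[1],
      T = .data$T[1],
      n_surv = sum(.data$alive1 & .data$alive2),
      n_recruit = sum(!.data$alive1 & .data$alive2),
      n_recruit_ha = sum(!.data$alive1 & .data$alive2) / .data$area_ha[1],
      N0 = sum(.data$alive1) / .data$area_ha[1],
      NT = sum(.data$alive2) / .data$area_ha[1],
      Wmax = max(c(.data$w1[.data$alive1], .data$w2[.data$alive2])),
      .groups = "drop"
    ) |>
    mutate(is_aggregate = FALSE)
}

#' Pool rare species into one aggregate population per plot
#'
#' Species with at least `min_survivors` trees alive at both censuses are
#' kept as named populations; all rarer species in a plot are summed
#' component-wise (biomasses, counts) into a single aggregate population,
#' so that total plot biomass is conserved exactly.
#'
#' @param populations Output of [build_populations()].
#' @param min_survivors Minimum survivor count for a named population.
#' @param aggregate_code Species code given to the pooled population.
#' @return Populations tibble with `is_aggregate` set for pooled rows.
#' @export
aggregate_rare_species <- function(populations, min_survivors = 2,
                                   aggregate_code = "__aggregate__") {
  stopifnot(is.data.frame(populations))
  keep <- populations |> filter(.data$n_surv >= min_survivors)
  rare <- populations |> filter(.data$n_surv < min_survivors)
  if (!nrow(rare)) return(keep)
  agg <- rare |>
    group_by(.data$plot_id) |>
    summarise(
      species = aggregate_code,
      B0 = sum(.data$B0), BT = sum(.data$BT), Bsurv0 = sum(.data$Bsurv0),
      T = .data$T[1],
      n_surv = sum(.data$n_surv), n_recruit = sum(.data$n_recruit),
      n_recruit_ha = sum(.data$n_recruit_ha),
      N0 = sum(.data$N0), NT = sum(.data$NT),
      Wmax = max(.data$Wmax),
      .groups = "drop"
    ) |>
    mutate(is_aggregate = TRUE)
  bind_rows(keep, agg) |> arrange(.data$plot_id, .data$is_aggregate, .data$species)
}
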