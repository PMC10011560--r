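#' Configure an end-to-end productivity analysis
#'
#' Bundles the inputs and tuning constants of [run_pipeline()]. The
#' defaults are the analysis constants used throughout: reference biomass
#' 160 Mg C ha^-1 for between-biome productivity comparison, small-biomass
#' threshold 3 Mg C ha^-1, and 10,000 resampling draws for the replaced
#' data.
#'
#' @param census Path to the census CSV, or a tree-record tibble.
#' @param plots Path to the plot-metadata CSV, or a tibble.
#' @param allometry An [allometry_model()], or `NULL` when the census
#'   carries `w1`/`w2` masses directly.
#' @param reference_biomass Biomass (Mg C ha^-1) at which biome
#'   productivities are predicted.
#' @param small_biomass_threshold Threshold (Mg C ha^-1) for the
#'   small-biomass species share.
#' @param n_draws Resampling draws for [replace_productivity()].
#' @param seed Integer seed governing all randomness in the run.
#' @param contribution_method Passed to [contribution_ratio()].
#' @param out_dir Output directory for CSVs and the manifest, or `NULL`
#'   to skip writing.
#' @return A `run_config` list.
#' @export
run_config <- function(census, plots, allometry = NULL,
                       reference_biomass = 160,
                       small_biomass_threshold = 3,
                       n_draws = 10000, seed = 1,
                       contribution_method = "refit",
                       out_dir = NULL) {
  structure(
    list(census = census, plots = plots, allometry = allometry,
         reference_biomass = reference_biomass,
         small_biomass_threshold = small_biomass_threshold,
         n_draws = n_draws, seed = seed,
         contribution_method = contribution_method,
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full productivity analysis pipeline
#'
#' Orchestrates the end-to-end analysis: read and validate the census,
#' apply allometry if configured, assemble species populations and pool
#' rare species, compute instantaneous demographic rates and plot totals,
#' fit the scaling models (species p-B pooled and with plot intercepts,
#' p-Wmax, and plot-level P against B and MAT), project the two null
#' models, compute their contribution ratios, predict biome productivity
#' at the reference biomass, and derive the stepwise-reduction and
#' small-biomass-share summaries. Identical config and seed give identical
#' outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list: `populations`, `rates`, `plots`
#'   (plot-level table with null projections joined), `fits` (list of
#'   `power_law_fit` objects), `null` (projections + contribution ratios),
#'   `biome_predictions`, `stepwise`, `small_biomass`, `manifest`. When
#'   `out_dir` is set, species/plot tables, fit summaries and the manifest
#'   are also written there as CSV/JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  records <- if (is.character(config$census)) {
    read_census_table(config$census)
  } else {
    as_tibble(config$census)
  }
  meta <- if (is.character(config$plots)) {
    read_plot_metadata(config$plots)
  } else {
    as_tibble(config$plots)
  }
  if (!"biome" %in% names(meta)) meta$biome <- classify_biome(meta$mat_c)
  thr_mass <- NULL
  if (!is.null(config$allometry)) {
    records <- apply_allometry(records, config$allometry)
    thr_mass <- threshold_mass(config$allometry)
  }
  pops <- build_populations(records, plot_area = meta) |>
    aggregate_rare_species()
  rates <- species_rates(pops, recruit_threshold_mass = thr_mass)
  plots <- forest_totals(rates, plot_meta = meta)

  fit_data <- filter_for_fitting(rates)
  excluded <- attr(fit_data, "excluded")
  fit_data <- left_join(fit_data, meta[, c("plot_id", "mat_c")], by = "plot_id")
  n_plots <- dplyr::n_distinct(fit_data$plot_id)
  fits <- list(
    pB = fit_power_law(fit_data, p, B),
    pB_plot = if (n_plots >= 2) {
      fit_power_law(fit_data, p, B, plot = plot_id, plot_intercepts = TRUE)
    },
    pWmax = fit_power_law(fit_data, p, Wmax),
    PBmat = fit_power_law(plots, P, B, mat_c)
  )

  null <- list()
  if (!is.null(fits$pB_plot)) {
    spec_res <- species_response_projection(
      rates, b = fits$pB_plot$b, a_plot = fits$pB_plot$plot_intercepts)
    replaced <- replace_productivity(rates, n_draws = config$n_draws,
                                     seed = config$seed)
    comm_str <- community_structure_projection(replaced)
    plots <- plots |>
      left_join(spec_res, by = "plot_id") |>
      left_join(comm_str, by = "plot_id")
    null$P_specRes <- spec_res
    null$P_commStr <- comm_str
    null$fit_specRes <- fit_power_law(plots, P_specRes, B, mat_c)
    null$fit_commStr <- fit_power_law(plots, P_commStr, B, mat_c)
    null$contribution_specRes <- contribution_ratio(
      plots, P_specRes, method = config$contribution_method)
    null$contribution_commStr <- contribution_ratio(
      plots, P_commStr, method = config$contribution_method)
  }

  biome_mat <- plots |>
    group_by(.data$biome) |>
    summarise(mat_c = mean(.data$mat_c), .groups = "drop")
  biome_predictions <- dplyr::bind_cols(
    biome = biome_mat$biome,
    predict_at(fits$PBmat, x = config$reference_biomass,
               mat = biome_mat$mat_c)
  )

  stepwise <- stepwise_reduction_curve(rates)
  small <- small_biomass_contribution(rates,
                                      threshold = config$small_biomass_threshold)
  plots <- left_join(plots, small, by = "plot_id")

  manifest <- list(
    package_version = as.character(utils::packageVersion("forestprod")),
    seed = config$seed,
    n_draws = config$n_draws,
    reference_biomass = config$reference_biomass,
    small_biomass_threshold = config$small_biomass_threshold,
    contribution_method = config$contribution_method,
    n_plots = nrow(plots),
    n_populations = nrow(rates),
    n_rejected_rows = nrow(attr(records, "rejected") %||% tibble()),
    fitting_exclusions = as.list(excluded)
  )
  inform(paste0("run_pipeline: ", manifest$n_plots, " plots, ",
                manifest$n_populations, " populations (",
                excluded$n_aggregate, " aggregated, ",
                excluded$n_excluded_nonpositive,
                " non-positive-p excluded from fitting)"))

  result <- list(populations = pops, rates = rates, plots = plots,
                 fits = fits, null = null,
                 biome_predictions = biome_predictions,
                 stepwise = stepwise, small_biomass = small,
                 manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    readr::write_csv(df, file.path(out_dir, paste0(name, ".csv")))
  }
  w(result$rates, "species_populations")
  w(result$plots, "plots")
  w(result$stepwise, "stepwise_reduction")
  w(result$biome_predictions, "biome_predictions")
  fit_tab <- purrr::imap_dfr(
    Filter(Negate(is.null), result$fits),
    function(f, nm) dplyr::bind_cols(model = nm, glance(f),
                                     tidyr::pivot_wider(tidy(f),
                                       names_from = "term",
                                       values_from = c("estimate", "std.error")))
  )
  w(fit_tab, "fit_summaries")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
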