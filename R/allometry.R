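#' Define a diameter-to-carbon-mass allometry
#'
#' Constructs a log-polynomial allometric model mapping stem diameter at
#' breast height (cm) to individual-tree aboveground carbon mass (Mg C).
#' Oven-dry mass is modelled as
#' \deqn{W_{dry}(d) = \rho \exp\{c_0 + c_1 \ln d + c_2 (\ln d)^2 + \dots\}}
#' where \eqn{\rho} is a wood-density multiplier resolved per tree through a
#' species -> genus -> family -> lifeform fallback chain, and carbon mass is
#' `carbon_factor` times dry mass (the standard 0.5 conversion from oven-dry
#' mass to carbon).
#'
#' @param coefficients Numeric vector `c(c0, c1, c2, ...)` of the
#'   log-polynomial in `ln d`. The default `c(0, 1)` is the identity map
#'   (dry mass equals diameter), useful for testing.
#' @param wood_density Either a single numeric multiplier applied to every
#'   tree, or a data frame with columns `level` (one of `"species"`,
#'   `"genus"`, `"family"`, `"lifeform"`), `name`, and `density` used as a
#'   lookup table with the fallback order species, genus, family, lifeform.
#' @param carbon_factor Conversion from oven-dry mass to carbon mass;
#'   fixed at 0.5 in the field and in all shipped presets.
#' @param valid_range Diameter range (cm) over which the model must be
#'   strictly increasing; checked at construction.
#'
#' @return An object of class `allometry_model`.
#' @examples
#' m <- allometry_model(c(-2, 2.5))
#' predict_dry_mass(m, 10) # exp(-2 + 2.5 * log(10))
#' @export
allometry_model <- function(coefficients = c(0, 1), wood_density = 1,
                            carbon_factor = 0.5,
                            valid_range = c(5, 300)) {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1,
            is.numeric(carbon_factor), carbon_factor > 0)
  if (is.data.frame(wood_density)) {
    need <- c("level", "name", "density")
    if (!all(need %in% names(wood_density))) {
      abort(paste0("wood_density table needs columns: ",
                   paste(need, collapse = ", ")))
    }
    bad <- setdiff(unique(wood_density$level),
                   c("species", "genus", "family", "lifeform"))
    if (length(bad)) {
      abort(paste0("unknown wood_density level(s): ",
                   paste(bad, collapse = ", ")))
    }
  } else {
    stopifnot(is.numeric(wood_density), length(wood_density) == 1,
              wood_density > 0)
  }
  m <- structure(
    list(coefficients = as.numeric(coefficients),
         wood_density = wood_density,
         carbon_factor = carbon_factor,
         valid_range = as.numeric(valid_range)),
    class = "allometry_model"
  )
  d <- exp(seq(log(valid_range[1]), log(valid_range[2]), length.out = 200))
  w <- dry_mass_kernel(m, d)
  if (any(diff(w) <= 0)) {
    abort("allometry_model: predicted mass is not strictly increasing in diameter over valid_range")
  }
  m
}

# polynomial-in-log(d) kernel, density excluded
dry_mass_kernel <- function(model, d_cm) {
  ld <- log(d_cm)
  k <- model$coefficients
  acc <- rep(k[1], length(ld))
  if (length(k) > 1) {
    for (j in seq_along(k)[-1]) acc <- acc + k[j] * ld^(j - 1)
  }
  exp(acc)
}

#' Predict oven-dry aboveground mass from diameter
#'
#' @param model An [allometry_model()].
#' @param d_cm Stem diameter(s) at breast height, cm.
#' @param density Optional per-tree wood-density multiplier; defaults to 1
#'   when the model's `wood_density` is a table (use
#'   [resolve_wood_density()] first) or to the model's scalar density.
#' @return Dry mass in Mg.
#' @export
predict_dry_mass <- function(model, d_cm, density = NULL) {
  stopifnot(inherits(model, "allometry_model"))
  if (is.null(density)) {
    density <- if (is.data.frame(model$wood_density)) 1 else model$wood_density
  }
  density * dry_mass_kernel(model, d_cm)
}

#' Resolve wood density through the taxonomic fallback chain
#'
#' Looks each tree up in the model's wood-density table at species level
#' first, then genus, family, and lifeform. A tree for which no level
#' resolves is a configuration error.
#'
#' @param model An [allometry_model()] whose `wood_density` is a lookup table.
#' @param species,genus,family,lifeform Character vectors (recycled scalars
#'   allowed); `NA` entries skip that level.
#' @return Numeric vector of densities.
#' @export
resolve_wood_density <- function(model, species, genus = NA, family = NA,
                                 lifeform = NA) {
  if (!is.data.frame(model$wood_density)) {
    return(rep(model$wood_density, length(species)))
  }
  tab <- model$wood_density
  n <- length(species)
  ids <- tibble(species = as.character(species),
                genus = rep_len(as.character(genus), n),
                family = rep_len(as.character(family), n),
                lifeform = rep_len(as.character(lifeform), n))
  out <- rep(NA_real_, n)
  for (lev in c("species", "genus", "family", "lifeform")) {
    sub <- tab[tab$level == lev, ]
    if (!nrow(sub)) next
    idx <- match(ids[[lev]], sub$name)
    fill <- is.na(out) & !is.na(idx)
    out[fill] <- sub$density[idx[fill]]
  }
  if (anyNA(out)) {
    miss <- unique(ids$species[is.na(out)])
    abort(paste0("wood density unresolvable (no lifeform fallback) for: ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  out
}

#' Fill tree carbon masses from diameters
#'
#' Applies an allometric model to a two-census tree table, filling `w1` and
#' `w2` (aboveground carbon mass, Mg C) exactly where the tree is alive at
#' the corresponding census. Rows that already carry masses are left
#' untouched unless `overwrite = TRUE`.
#'
#' @param records Tree-record tibble from [read_census_table()] (columns
#'   `d1_cm`, `d2_cm`, `alive1`, `alive2`; optional `genus`, `family`,
#'   `lifeform` for density lookup).
#' @param model An [allometry_model()].
#' @param overwrite Recompute masses even where present.
#' @return The records tibble with `w1`, `w2` filled.
#' @export
apply_allometry <- function(records, model, overwrite = FALSE) {
  stopifnot(is.data.frame(records), inherits(model, "allometry_model"))
  records <- as_tibble(records)
  if (!"w1" %in% names(records)) records$w1 <- NA_real_
  if (!"w2" %in% names(records)) records$w2 <- NA_real_
  dens <- resolve_wood_density(
    model,
    species = records$species,
    genus = records$genus %||% NA,
    family = records$family %||% NA,
    lifeform = records$lifeform %||% NA
  )
  f1 <- records$alive1 & (overwrite | is.na(records$w1))
  f2 <- records$alive2 & (overwrite | is.na(records$w2))
  cf <- model$carbon_factor
  records$w1[f1] <- cf * dens[f1] * dry_mass_kernel(model, records$d1_cm[f1])
  records$w2[f2] <- cf * dens[f2] * dry_mass_kernel(model, records$d2_cm[f2])
  records$w1[!records$alive1] <- NA_real_
  records$w2[!records$alive2] <- NA_real_
  records
}

#' Carbon mass of a tree at the recruitment threshold
#'
#' Convenience for the simple-productivity recruit convention: the mass a
#' tree has when it crosses the minimum census diameter (5 cm by default).
#'
#' @inheritParams apply_allometry
#' @param threshold_cm Census diameter threshold, cm.
#' @param density Wood-density multiplier for the threshold tree.
#' @return Carbon mass (Mg C) at the threshold diameter.
#' @export
threshold_mass <- function(model, threshold_cm = 5, density = NULL) {
  model$carbon_factor * predict_dry_mass(model, threshold_cm, density)
}
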