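# Shared fixtures and independent oracles for the suite.

# Independent ordinary-least-squares oracle: normal equations, no lm().
ne_ols <- function(X, y) {
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# A minimal population row with sensible defaults.
make_pop <- function(plot_id = "p1", species = "sp1",
                     B0 = 100, BT = 110, Bsurv0 = 95, T = 5,
                     n_surv = 5, n_recruit = 0, n_recruit_ha = 0,
                     N0 = 10, NT = 10, Wmax = 1, is_aggregate = FALSE) {
  tibble::tibble(plot_id = plot_id, species = species, B0 = B0, BT = BT,
                 Bsurv0 = Bsurv0, T = T, n_surv = n_surv,
                 n_recruit = n_recruit, n_recruit_ha = n_recruit_ha,
                 N0 = N0, NT = NT, Wmax = Wmax, is_aggregate = is_aggregate)
}

# Randomised multi-species population table with exponential-dynamics
# structure (Bsurv0 <= B0, all positive), for conservation/oracle tests.
random_pops <- function(n_species = 20, plot_id = "p1", seed = 42) {
  withr::with_seed(seed, {
    B0 <- rlnorm(n_species, 0, 1.5)
    surv_frac <- runif(n_species, 0.5, 1)
    growth <- runif(n_species, -0.1, 0.5)
    tibble::tibble(
      plot_id = plot_id,
      species = paste0("sp", seq_len(n_species)),
      B0 = B0,
      Bsurv0 = B0 * surv_frac,
      BT = B0 * surv_frac * exp(growth),
      T = 5,
      n_surv = sample(0:6, n_species, replace = TRUE),
      n_recruit = 0L, n_recruit_ha = 0,
      N0 = sample(1:30, n_species, replace = TRUE),
      NT = sample(1:30, n_species, replace = TRUE),
      Wmax = rlnorm(n_species, -1, 1),
      is_aggregate = FALSE
    )
  })
}

# Write a census CSV and return its path.
write_census_csv <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "census.csv")
  writeLines(lines, path)
  path
}

# Species table from the synthetic generator reshaped as a rates table
# (one "plot" per stand), for exercising the null models on known laws.
rates_from_species_table <- function(species_table) {
  dplyr::mutate(species_table,
                plot_id = stand,
                P = p * B,
                is_aggregate = FALSE,
                valid_p = p > 0)
}
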