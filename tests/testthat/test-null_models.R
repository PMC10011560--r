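test_that("species-response projection matches Eq-style hand evaluations", {
  # single plot, equal species biomasses, exact power law: projection = P
  a1 <- 1.3; b <- -0.4; beta <- 2; S <- 5
  rates <- tibble::tibble(
    plot_id = "p1", species = paste0("s", 1:S),
    B = beta, p = a1 * beta^b, P = a1 * beta^(1 + b),
    is_aggregate = FALSE
  )
  proj <- species_response_projection(rates, b = b,
                                      a_plot = tibble::tibble(plot_id = "p1", a = a1))
  expect_equal(proj$P_specRes, sum(rates$P), tolerance = 1e-12)

  # two-plot toy with hand-computed shared ratio
  rates2 <- tibble::tibble(
    plot_id = c("p1", "p1", "p2"), species = c("s1", "s2", "s3"),
    B = c(1, 2, 4), p = 0.1, P = 0.1 * c(1, 2, 4), is_aggregate = FALSE
  )
  ap <- tibble::tibble(plot_id = c("p1", "p2"), a = c(1, 2))
  proj2 <- species_response_projection(rates2, b = -0.5, a_plot = ap)
  ratio <- (1 + 2^0.5 + 4^0.5) / 7
  expect_equal(ratio, 0.63060, tolerance = 1e-4)
  expect_equal(proj2$P_specRes[proj2$plot_id == "p1"], 1 * 3 * ratio,
               tolerance = 1e-12)
  expect_equal(round(proj2$P_specRes[proj2$plot_id == "p1"], 4), 1.8918)
  expect_equal(proj2$P_specRes[proj2$plot_id == "p2"], 2 * 4 * ratio,
               tolerance = 1e-12)

  # b = 0: ratio collapses to 1 and the projection is a_plot * B
  proj0 <- species_response_projection(rates2, b = 0, a_plot = ap)
  expect_equal(proj0$P_specRes, c(1 * 3, 2 * 4))

  # plot ordering does not matter (associativity of the double sum)
  shuf <- species_response_projection(rates2[c(3, 1, 2), ], b = -0.5,
                                      a_plot = ap[2:1, ])
  expect_equal(dplyr::arrange(shuf, plot_id), dplyr::arrange(proj2, plot_id))

  # aggregates: excluded from the double sum, their own P added unchanged
  with_agg <- dplyr::bind_rows(
    rates2, tibble::tibble(plot_id = "p1", species = "__aggregate__",
                           B = 0.5, p = 0.2, P = 0.1, is_aggregate = TRUE))
  proja <- species_response_projection(with_agg, b = -0.5, a_plot = ap)
  expect_equal(proja$P_specRes[proja$plot_id == "p1"], 1 * 3 * ratio + 0.1,
               tolerance = 1e-12)

  expect_error(
    species_response_projection(rates2, b = -0.5, a_plot = ap[1, ]),
    "no a_plot"
  )
})

test_that("biomass-similarity replacement obeys its closed form and determinism", {
  # constant donor pool: replacement returns the constant for any weights
  const <- tibble::tibble(
    plot_id = "p1", species = paste0("s", 1:4),
    B = c(1, 2, 4, 8), P = 0.7, p = 0.7 / c(1, 2, 4, 8), is_aggregate = FALSE
  )
  rep1 <- replace_productivity(const, n_draws = 50, seed = 1)
  expect_equal(rep1$P_replaced, rep(0.7, 4))

  # 3-candidate pool: deterministic mode equals the hand-computed expectation
  pool <- tibble::tibble(
    plot_id = c("p1", "p1", "p2", "p2"), species = paste0("s", 1:4),
    B = c(1, 2, 4, 8), P = c(0.1, 0.3, 0.2, 0.5),
    p = 1, is_aggregate = FALSE
  )
  det <- replace_productivity(pool, deterministic = TRUE)
  w <- 1 / (log(c(2, 4, 8)) - log(1))^2
  expect_equal(det$P_replaced[1], sum(w * c(0.3, 0.2, 0.5)) / sum(w),
               tolerance = 1e-12)

  # Monte-Carlo mean converges to the closed form (law of large numbers)
  mc <- replace_productivity(pool, n_draws = 1e5, seed = 7)
  w1 <- w / sum(w)
  se <- sqrt((sum(w1 * c(0.3, 0.2, 0.5)^2) -
                sum(w1 * c(0.3, 0.2, 0.5))^2) / 1e5)
  expect_lt(abs(mc$P_replaced[1] - det$P_replaced[1]), 3 * se)

  # bit-reproducible for a fixed seed; seeding does not leak to the session
  r1 <- replace_productivity(pool, n_draws = 200, seed = 42)
  r2 <- replace_productivity(pool, n_draws = 200, seed = 42)
  expect_identical(r1$P_replaced, r2$P_replaced)

  # draw-noise SD scales as 1/sqrt(n_draws)
  sd_at <- function(nd) {
    sd(vapply(1:120, function(s) {
      replace_productivity(pool, n_draws = nd, seed = s)$P_replaced[1]
    }, numeric(1)))
  }
  expect_equal(sd_at(100) / sd_at(1600), 4, tolerance = 0.3)

  # exact log-biomass ties are sampled uniformly among themselves
  tied <- tibble::tibble(
    plot_id = "p1", species = paste0("s", 1:4),
    B = c(2, 2, 2, 50), P = c(0.1, 0.4, 0.6, 9), p = 1, is_aggregate = FALSE
  )
  dt <- replace_productivity(tied, deterministic = TRUE)
  expect_equal(dt$P_replaced[1], mean(c(0.4, 0.6)))

  expect_error(replace_productivity(const[1, ]), "at least two")
})

test_that("community-structure projection sums replaced values plus aggregates", {
  rates <- tibble::tibble(
    plot_id = "p1", species = c("a", "b", "agg"),
    B = c(1, 2, 0.2), P = c(0.8, 1.2, 0.5), p = 1,
    is_aggregate = c(FALSE, FALSE, TRUE),
    P_replaced = c(1.0, 2.0, NA)
  )
  expect_equal(community_structure_projection(rates)$P_commStr, 3.5)

  # identity replacement recovers plot P exactly
  ident <- dplyr::mutate(rates, P_replaced = ifelse(is_aggregate, NA, P))
  expect_equal(community_structure_projection(ident)$P_commStr, sum(rates$P))

  # randomised fixture equals independent re-summation
  rnd <- rates_from_species_table(
    generate_species_table(synthetic_forest_spec(n_stands = 3,
                                                 species_richness = 12),
                           seed = 4)) |>
    replace_productivity(deterministic = TRUE)
  got <- community_structure_projection(rnd)
  want <- tapply(rnd$P_replaced, rnd$plot_id, sum)
  expect_equal(got$P_commStr, as.numeric(want[got$plot_id]))
})

test_that("replacement among duplicated communities under one law restores P exactly", {
  # two plots with identical biomass spectra and a single global power law:
  # every population's only same-lnB donor carries the same P, so the
  # deterministic replacement leaves plot productivity unchanged
  B <- exp(seq(-2, 2, length.out = 8))
  a <- 0.5; b <- -0.3
  rates <- tidyr::expand_grid(plot_id = c("p1", "p2"), B = B) |>
    dplyr::mutate(species = paste0("s", dplyr::row_number()),
                  p = a * B^b, P = p * B, is_aggregate = FALSE)
  out <- replace_productivity(rates, deterministic = TRUE) |>
    community_structure_projection()
  expect_equal(out$P_commStr, rep(sum(a * B^(1 + b)), 2), tolerance = 1e-12)
})

test_that("contribution ratio hits its stated boundaries and a constructed midpoint", {
  withr::with_seed(31, {
    plots <- tibble::tibble(
      B = rlnorm(40, 5, 0.4),
      mat_c = runif(40, 0, 26)
    )
    plots$P <- exp(-1 + 0.4 * log(plots$B) + 0.04 * plots$mat_c +
                     rnorm(40, 0, 0.25))
  })
  lnP <- log(plots$P)
  orig <- lm(lnP ~ log(plots$B) + plots$mat_c)

  # null identical to the original model's predictions -> 1
  plots$null_same <- exp(fitted(orig))
  expect_equal(contribution_ratio(plots, null_same, method = "direct"), 1,
               tolerance = 1e-12)
  expect_equal(contribution_ratio(plots, null_same, method = "refit"), 1,
               tolerance = 1e-12)

  # null equal to mean(ln P) -> 0
  plots$null_flat <- exp(mean(lnP))
  expect_equal(contribution_ratio(plots, null_flat, method = "direct"), 0,
               tolerance = 1e-12)

  # constructed null explaining exactly half the explained variance -> 0.5
  f <- fitted(orig)
  alpha <- 1 - 1 / sqrt(2)
  plots$null_half <- exp(mean(lnP) + alpha * (f - mean(lnP)))
  expect_equal(contribution_ratio(plots, null_half, method = "direct"), 0.5,
               tolerance = 1e-10)

  # degenerate observed model -> NA with a warning
  flat <- tibble::tibble(B = 1, mat_c = 1, P = exp(c(1, 1, 1, 1)))
  flat$null <- 1
  expect_warning(cr <- contribution_ratio(flat, null), "undefined")
  expect_true(is.na(cr))
})
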