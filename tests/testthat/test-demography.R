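test_that("instantaneous rate estimators match their closed forms", {
  expect_equal(relative_productivity(100, 100, 5), 0)
  expect_equal(relative_productivity(110, 100, 5), log(1.1) / 5)
  expect_equal(round(relative_productivity(110, 100, 5), 6), 0.019062)
  # 1/T scaling: same ratio over twice the interval halves the rate
  expect_equal(relative_productivity(110, 100, 10),
               relative_productivity(110, 100, 5) / 2)

  expect_equal(relative_loss(100, 100, 5), 0)
  expect_equal(round(relative_loss(100, 80, 5), 6), 0.044629)
  expect_equal(relative_loss(100, 50, log(2)), 1)

  # undefined when no surviving biomass
  expect_true(is.na(relative_productivity(10, 0, 5)))
  expect_true(is.na(relative_loss(10, 0, 5)))
})

test_that("period-mean biomass is the logarithmic mean with its limit and bounds", {
  expect_equal(period_mean_biomass(100, 100), 100)
  expect_equal(period_mean_biomass(100, 150), 50 / log(1.5))
  expect_equal(round(period_mean_biomass(100, 150), 3), 123.315)
  expect_equal(period_mean_biomass(150, 100), period_mean_biomass(100, 150))
  # log-mean inequality over random positive pairs
  withr::with_seed(11, {
    x <- rlnorm(200, 0, 2); y <- rlnorm(200, 0, 2)
    bm <- period_mean_biomass(x, y)
    expect_true(all(bm >= pmin(x, y) & bm <= pmax(x, y)))
    expect_true(all(bm <= (x + y) / 2 + 1e-12))
  })
  # near-equal arguments hit the arithmetic-mean continuation smoothly
  expect_equal(period_mean_biomass(100, 100 * (1 + 1e-12)), 100,
               tolerance = 1e-9)
})

test_that("period-mean abundance handles zero counts by stated policy", {
  expect_equal(period_mean_abundance(12, 12), 12)
  expect_equal(period_mean_abundance(10, 20), 10 / log(2))
  expect_equal(round(period_mean_abundance(10, 20), 3), 14.427)
  expect_warning(n <- period_mean_abundance(0, 4), "arithmetic")
  expect_equal(n, 2)
  expect_equal(suppressWarnings(period_mean_abundance(0, 0)), 0)
})

test_that("forest totals equal brute-force sums and count species correctly", {
  r1 <- species_rates(make_pop(B0 = 100, BT = 100 * exp(0.02 * 5),
                               Bsurv0 = 100))
  expect_equal(r1$P, 0.02 * r1$B)
  t1 <- forest_totals(r1)
  expect_equal(t1$P, r1$P)

  pops <- dplyr::bind_rows(
    make_pop(species = "a", B0 = 100, Bsurv0 = 100, BT = 110),
    make_pop(species = "b", B0 = 80, Bsurv0 = 70, BT = 78)
  )
  r2 <- species_rates(pops)
  expect_equal(forest_totals(r2)$P, sum(r2$p * r2$B))

  # randomised fixture against independent re-summation
  rnd <- species_rates(random_pops(30))
  tot <- forest_totals(rnd)
  expect_equal(tot$P, sum(rnd$p * rnd$B), tolerance = 1e-12)
  expect_equal(tot$L, sum(rnd$l * rnd$B), tolerance = 1e-12)
  expect_equal(tot$B, sum(rnd$B), tolerance = 1e-12)
  expect_equal(tot$SR, 30L)

  # the aggregate is one population but zero species in SR
  withagg <- species_rates(dplyr::bind_rows(
    random_pops(5), make_pop(species = "__aggregate__", is_aggregate = TRUE)))
  expect_equal(forest_totals(withagg)$SR, 5L)
})

test_that("net change identity: P - L equals (BT - B0)/T for every plot", {
  rnd <- species_rates(random_pops(25, seed = 99))
  tot <- forest_totals(rnd)
  expect_equal(tot$P - tot$L, sum(rnd$BT - rnd$B0) / rnd$T[1],
               tolerance = 1e-12)
})

test_that("the simple estimator matches arithmetic and is biased low under turnover", {
  r <- species_rates(make_pop(BT = 110, Bsurv0 = 90, B0 = 100, T = 5))
  expect_equal(r$P_simple, 4)
  r0 <- species_rates(make_pop(BT = 90, Bsurv0 = 90, B0 = 100, T = 5))
  expect_equal(r0$P_simple, 0)

  # grid oracle over (p, l, T): equality at l = 0, strict underestimate for l > 0
  grid <- expand.grid(p = c(0.02, 0.05, 0.1), l = c(0, 0.01, 0.04),
                      T = c(2.5, 5, 8.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    B0 <- 100
    Bsurv0 <- B0 * exp(-g$l * g$T)
    BT <- Bsurv0 * exp(g$p * g$T)
    r <- species_rates(make_pop(B0 = B0, Bsurv0 = Bsurv0, BT = BT, T = g$T))
    expect_equal(r$p, g$p, tolerance = 1e-12)
    expect_equal(r$l, g$l, tolerance = 1e-12)
    if (g$l == 0) {
      expect_equal(r$P_simple, r$P, tolerance = 1e-12)
    } else {
      expect_lt(r$P_simple, r$P)
    }
  }
})

test_that("recruit threshold-mass convention reduces the simple estimate", {
  pop <- make_pop(BT = 110, Bsurv0 = 90, n_recruit = 4, n_recruit_ha = 4)
  with_thr <- species_rates(pop, recruit_threshold_mass = 0.05)
  without <- species_rates(pop)
  expect_equal(without$P_simple - with_thr$P_simple, 4 * 0.05 / 5)
})

test_that("fitting filter excludes aggregates and non-positive p with a count", {
  pops <- dplyr::bind_rows(
    make_pop(species = "a", BT = 110, Bsurv0 = 100),            # p > 0
    make_pop(species = "b", BT = 99, Bsurv0 = 100, B0 = 100),   # p < 0
    make_pop(species = "c", BT = 105, Bsurv0 = 100),            # p > 0
    make_pop(species = "agg", is_aggregate = TRUE)
  )
  r <- species_rates(pops)
  expect_message(keep <- filter_for_fitting(r), "kept 2 of 3")
  expect_equal(nrow(keep), 2)
  ex <- attr(keep, "excluded")
  expect_equal(ex$n_excluded_nonpositive, 1)
  expect_equal(ex$n_aggregate, 1)

  # constructed 10% non-positive fixture reports that fraction
  ten <- dplyr::bind_rows(lapply(1:10, function(i) {
    make_pop(species = paste0("s", i),
             BT = if (i == 1) 95 else 110, Bsurv0 = 100, B0 = 100)
  }))
  keep10 <- suppressMessages(filter_for_fitting(species_rates(ten)))
  expect_equal(attr(keep10, "excluded")$fraction_excluded, 0.1)
})

test_that("stepwise removal of small-biomass species tracks remaining P", {
  # three species ordered by B with P_i = 1, 2, 3
  pops <- dplyr::bind_rows(
    make_pop(species = "s1", B0 = 10, BT = 10, Bsurv0 = 10 * exp(-0.1 / 10 * 5)),
    make_pop(species = "s2", B0 = 20, BT = 20, Bsurv0 = 20 * exp(-0.1 / 10 * 5)),
    make_pop(species = "s3", B0 = 30, BT = 30, Bsurv0 = 30 * exp(-0.1 / 15 * 5))
  )
  r <- species_rates(pops) |>
    dplyr::mutate(B = c(10, 20, 30), P = c(1, 2, 3), p = P / B)
  curve <- stepwise_reduction_curve(r)
  expect_equal(curve$P_remaining, c(6, 5, 3))
  expect_equal(curve$n_removed, 0:2)

  single <- stepwise_reduction_curve(species_rates(make_pop()))
  expect_equal(nrow(single), 1)

  rnd <- species_rates(random_pops(15, seed = 3))
  crv <- stepwise_reduction_curve(rnd)
  expect_equal(crv$P_remaining[nrow(crv)],
               rnd$P[which.max(rnd$B)], tolerance = 1e-12)
  # non-increasing when all P_i >= 0
  pos <- dplyr::mutate(rnd, P = abs(P))
  expect_true(all(diff(stepwise_reduction_curve(pos)$P_remaining) <= 1e-12))
})

test_that("small-biomass species share hits its boundaries and a constructed value", {
  small <- species_rates(dplyr::bind_rows(
    make_pop(species = "a", B0 = 1, BT = 1.1, Bsurv0 = 1),
    make_pop(species = "b", B0 = 2, BT = 2.1, Bsurv0 = 2)
  ))
  expect_equal(small_biomass_contribution(small)$small_biomass_fraction, 1)

  big <- species_rates(make_pop(B0 = 50, BT = 55, Bsurv0 = 50))
  expect_equal(small_biomass_contribution(big)$small_biomass_fraction, 0)

  # constructed plot with a known 37% small-biomass share
  mixed <- species_rates(dplyr::bind_rows(
    make_pop(species = "sm", B0 = 2, BT = 2, Bsurv0 = 2),
    make_pop(species = "lg", B0 = 100, BT = 100, Bsurv0 = 100)
  )) |>
    dplyr::mutate(P = c(0.37, 0.63))
  expect_equal(small_biomass_contribution(mixed)$small_biomass_fraction, 0.37)
})

test_that("ANPP adds annualised litter fall to woody productivity", {
  expect_equal(anpp(2, 3), 5)
  expect_equal(anpp(2, 0), 2)
  expect_equal(annual_litter(rep(0.25, 12)), 3)
  expect_equal(anpp(2, annual_litter(rep(0.25, 24))), 5)
})
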