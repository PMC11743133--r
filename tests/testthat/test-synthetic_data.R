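test_that("generators are bit-reproducible and carry their parameterization", {
  d <- design_spec(seed = 123)
  e <- effect_spec()
  expect_identical(generate_line_traits(d, e), generate_line_traits(d, e))
  expect_identical(generate_consumption(d, e, 30, 3),
                   generate_consumption(d, e, 30, 3))
  expect_identical(generate_expression(d, e), generate_expression(d, e))
  expect_identical(attr(generate_line_traits(d, e), "generator")$design$seed,
                   123L)
})

test_that("the design matches the 12-line + 3-ancestor layout", {
  d <- design_spec()
  expect_identical(nrow(d$lines), 15L)
  expect_identical(sum(d$lines$regime == "ancestor"), 3L)
  expect_identical(sum(d$lines$regime == "hot"), 6L)
  expect_setequal(unique(d$lines$origin), c("Brazil", "California", "Yemen"))
  expect_identical(d$assay_temps_C, c(23, 29, 35))
})

test_that("null effects reproduce the baseline exactly", {
  d <- design_spec(origins = "X", seed = 1)
  e <- effect_spec(trait_cv = 0, line_scale_sd = 0,
                   origin_scale = c(X = 1))
  tr <- generate_line_traits(d, e)
  anc <- tr[tr$regime == "ancestor", ]
  i <- match(anc$assay_temp_C, d$assay_temps_C)
  expect_equal(anc$omega_mean, e$baseline$omega[i], tolerance = 1e-12)
  expect_equal(anc$mass_M_mean, e$baseline$mass_M[i], tolerance = 1e-12)
  expect_equal(anc$d1_mean, e$baseline$d1[i], tolerance = 1e-12)
  expect_true(all(tr$omega_se == 0))
})

test_that("survivors never exceed eggs and masses stay positive", {
  for (seed in c(1, 7, 99)) {
    cons <- generate_consumption(design_spec(seed = seed), effect_spec(), 50, 4)
    expect_true(all(cons$assays$survivors <= cons$assays$eggs))
    expect_true(all(cons$assays$mean_adult_mass > 0))
    expect_true(all(cons$assays$host_loss_raw >= 0))
  }
})

test_that("noiseless consumption recovers the generating slope exactly", {
  e <- effect_spec(residual_cv = 0, control_drift = 0, control_sd = 0)
  cons <- generate_consumption(design_spec(seed = 3), e, 40, 3)
  assays <- control_correct(cons$assays, cons$controls)
  for (Tc in c(23, 29, 35)) {
    est <- suppressWarnings(estimate_Cm(assays[assays$assay_temp_C == Tc, ]))
    expect_equal(est$C_m, e$C_m[[as.character(Tc)]], tolerance = 1e-9)
  }
})

test_that("the footprint pipeline recovers the configured +80% hot effect", {
  d <- design_spec(seed = 42)
  e <- effect_spec()
  tr <- generate_line_traits(d, e)
  fp <- footprint_estimates(tr, e$C_m, e$C_E, n_boot = 400, seed = 7)
  # ancestor self-reference at 29 C is exactly 0%
  anc29 <- fp$regime == "ancestor" & fp$assay_temp_C == 29
  expect_equal(fp$rel_phi1[anc29], rep(0, 3), tolerance = 1e-12)

  # hot-regime lines at 35 C: mean same-temperature evolution contrast
  # within 3 MC SEs of the generating +80%; cold at 23 C near +7.6%
  hot <- fp$evo_rel_phi1[fp$regime == "hot" & fp$assay_temp_C == 35]
  cold <- fp$evo_rel_phi1[fp$regime == "cold" & fp$assay_temp_C == 23]
  expect_lt(abs(mean(hot) - 80), 3 * stats::sd(hot) / sqrt(length(hot)))
  expect_lt(abs(mean(cold) - 7.6), 3 * stats::sd(cold) / sqrt(length(cold)))
})

test_that("phi1 and phi2 on the same process correlate strongly", {
  d <- design_spec(seed = 5)
  e <- effect_spec()   # trait CV 5% <= the 10% bound of the contract
  tr <- generate_line_traits(d, e)
  fp <- footprint_estimates(tr, e$C_m, e$C_E, n_boot = 1, seed = 1)
  expect_gte(footprint_correlation(fp$phi1, fp$phi2)$r, 0.8)
})

test_that("expression generator hits the configured quadrants and shift", {
  d <- design_spec(seed = 6)
  e <- effect_spec()
  ex <- generate_expression(d, e)
  cls <- classify_directions(ex$panel)
  expect_identical(cls$antagonistic, 134L)
  expect_identical(cls$concordant, 3L)
  expect_identical(unname(cls$quadrants["up_mating_down_heat"]), 21L)
  expect_identical(ncol(ex$counts), 54L)  # 12 lines x 3 T + 3 anc x 2 x 3 T

  sc <- tradeoff_scores(ex$panel, ex$counts)
  pr <- tradeoff_axis_projection(sc)
  by_T <- tapply(pr$projection, ex$samples$assay_temp_C, mean)
  expect_gt(by_T[["35"]], by_T[["23"]])
  expect_gt(by_T[["35"]], by_T[["29"]])
})

test_that("purely antagonistic mirrored panels give exact antisymmetry", {
  d <- design_spec(seed = 12)
  e <- effect_spec(n_concordant = 0, mirror_sd = 0)
  ex <- generate_expression(d, e)
  sc <- tradeoff_scores(ex$panel, ex$counts)
  expect_equal(sc$score_HS, -sc$score_R, tolerance = 1e-10)
  expect_lte(tradeoff_axis_projection(sc)$correlation, -0.99)
})

test_that("effect recovery holds across random effect configurations", {
  set.seed(71)
  for (i in 1:10) {
    slope <- stats::runif(1, 2.5, 4.5)
    e <- effect_spec(C_m = c(`23` = slope, `29` = slope, `35` = slope),
                     residual_cv = stats::runif(1, 0.02, 0.08))
    cons <- generate_consumption(design_spec(seed = 100 + i), e, 80, 4)
    assays <- control_correct(cons$assays, cons$controls)
    est <- estimate_Cm(assays[assays$assay_temp_C == 29, ])
    expect_lt(abs(est$C_m - slope), 3 * est$se + 0.02 * slope)
  }
})

test_that("model-implied traits bridge the model to the footprint pipeline", {
  p <- default_params()
  d <- design_spec(seed = 2)
  e <- effect_spec()
  tr <- generate_model_truth(p, d, e, fast_cfg())
  expect_true(all(tr$converged))
  map <- attr(tr, "mapping")

  # phi1 with C_m = 1 is exactly proportional to the model impact M* r'
  opts <- attr(tr, "optima")
  k <- map$s_omega * map$s_mass / map$d1
  for (i in sample(nrow(tr), 10)) {
    o <- opts[[tr$regime[i]]]
    imp <- agricultural_impact(celsius_to_kelvin(tr$assay_temp_C[i]),
                               o$strategy, p)
    got <- phi1(1, tr$omega_mean[i], tr$mass_M_mean[i], tr$d1_mean[i])
    expect_equal(got, k * imp, tolerance = 1e-9)
  }

  # hot-adapted footprint at 35 C exceeds cold-adapted at 35 C
  f35 <- phi1(1, tr$omega_mean, tr$mass_M_mean, tr$d1_mean)
  hot35 <- mean(f35[tr$regime == "hot" & tr$assay_temp_C == 35])
  cold35 <- mean(f35[tr$regime == "cold" & tr$assay_temp_C == 35])
  expect_gt(hot35, cold35)

  # with the strategy frozen across rows, footprint differences reflect only
  # the thermodynamic factors: ratio across temperatures equals the r' ratio
  anc <- tr[tr$regime == "ancestor" & tr$origin == d$origins[1], ]
  s <- opts$ancestor$strategy
  r_ratio <- growth_rate(celsius_to_kelvin(35), s, p)$r_prime /
    growth_rate(celsius_to_kelvin(23), s, p)$r_prime
  f_ratio <- anc$omega_mean[anc$assay_temp_C == 35] /
    anc$omega_mean[anc$assay_temp_C == 23]
  expect_equal(f_ratio, r_ratio, tolerance = 1e-9)
})
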