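test_that("arrhenius_rate matches the closed form and its limits", {
  expect_identical(arrhenius_rate(1, 0, 300), 1)
  # prefactor limit at very large T
  expect_equal(arrhenius_rate(5, 60000, 1e12), 5, tolerance = 1e-6)
  # frozen scalar evaluation, exp(-60000 / (8.314 * 298.15))
  expect_equal(arrhenius_rate(1, 60000, 298.15), 3.07517534168e-11,
               tolerance = 1e-9)
  expect_error(arrhenius_rate(1, 60000, -5), class = "tf_invalid_input")
  expect_error(arrhenius_rate(1, 60000, 0), class = "tf_invalid_input")
})

test_that("unfold_constant is 1 at the midpoint and follows dG_u", {
  p <- kinetic_params(dH_m = 4e5, T_m = 331.15, dCp = 0)
  expect_equal(unfold_constant(331.15, p), 1, tolerance = 1e-12)
  # curvature term does not move the midpoint
  p2 <- kinetic_params(dH_m = 4e5, T_m = 331.15, dCp = 8000)
  expect_equal(unfold_constant(331.15, p2), 1, tolerance = 1e-12)
  # essentially infinitely stable below the midpoint
  p3 <- kinetic_params(dH_m = 1e7, T_m = 331.15)
  expect_lt(unfold_constant(300, p3), 1e-100)
  # frozen scalar evaluation above the midpoint
  expect_equal(unfold_constant(333.15, p), 2.39216451103, tolerance = 1e-9)
})

test_that("stability_factor obeys its limits and frozen value", {
  p <- kinetic_params(kappa_D = 1, dH_m = 4e5, T_m = 331.15)
  # kappa_D / (q M) = 1 at the midpoint -> 1 / (1 + 1) = 0.5
  s <- strategy(M = 2, p = 0.25, q = 0.5)
  expect_equal(stability_factor(331.15, s, p), 0.5, tolerance = 1e-12)
  # q = 0 is the documented zero limit, not an error
  expect_identical(stability_factor(300, strategy(2, 0.5, 0), p), 0)
  p2 <- kinetic_params(kappa_D = 2, dH_m = 4e5, T_m = 331.15)
  expect_equal(stability_factor(333.15, strategy(4, 0.25, 0.25), p2),
               0.17288089875, tolerance = 1e-9)
})

test_that("juvenile_survival and productivity match closed forms", {
  expect_identical(juvenile_survival(10, 0), 1)
  expect_identical(juvenile_survival(0, 0.3), 1)
  expect_equal(juvenile_survival(10, 0.1), 0.3486784401, tolerance = 1e-12)
  expect_error(juvenile_survival(10, 1), class = "tf_invalid_input")
  expect_error(juvenile_survival(10, -0.1), class = "tf_invalid_input")

  expect_identical(productivity(strategy(3, 0.5, 0.5), 0.75), 0)
  expect_identical(productivity(strategy(4, 0, 0), 1), 4)
  expect_equal(productivity(strategy(4, 0.25, 0.25), 0.75), 2^0.75,
               tolerance = 1e-12)
})

test_that("growth_rate is the product of its four components", {
  params <- kinetic_params(a_B = 1, Ea_B = 60000, kappa_D = 2, dH_m = 4e5,
                           T_m = 331.15, c = 0.1, b = 0.75)
  s <- strategy(4, 0.25, 0.25)
  out <- growth_rate(302.15, s, params)
  # brute-force product of the independently exported component operations
  oracle <- juvenile_survival(4, 0.1) * productivity(s, 0.75) *
    arrhenius_rate(1 * 0.25 * 4, 60000, 302.15) *
    stability_factor(302.15, s, params)
  expect_equal(out$r_prime, oracle, tolerance = 1e-12)
  expect_identical(out$impact, 4 * out$r_prime)

  # boundary strategies give r' = 0
  expect_identical(growth_rate(302.15, strategy(4, 0, 0.25), params)$r_prime, 0)
  expect_identical(growth_rate(302.15, strategy(4, 0.25, 0), params)$r_prime, 0)
  expect_identical(growth_rate(302.15, strategy(4, 0.5, 0.5), params)$r_prime, 0)
})

test_that("r' components multiply to r' for 100 random valid inputs", {
  set.seed(11)
  for (i in 1:100) {
    params <- random_params()
    s <- random_strategy()
    out <- growth_rate(stats::runif(1, 280, 330), s, params)
    prod4 <- out$survival * out$productivity * out$reaction_rate *
      out$stability
    expect_equal(out$r_prime, prod4, tolerance = 1e-12)
    expect_identical(out$impact, s$M * out$r_prime)
  }
})

test_that("stability_factor is monotone in T and in q*M", {
  p <- kinetic_params(dH_m = 3e5, T_m = 315, dCp = 0, kappa_D = 5)
  s <- strategy(10, 0.3, 0.1)
  Tgrid <- seq(315 - 30, 315 + 30, by = 0.5)
  vals <- stability_factor(Tgrid, s, p)
  expect_true(all(diff(vals) <= 0))
  # increasing in q*M at fixed T
  qm <- seq(0.05, 3, by = 0.05)
  at_T <- vapply(qm, function(x)
    stability_factor(310, strategy(2 * x, 0.2, 0.5), p), numeric(1))
  expect_true(all(diff(at_T) > 0))
})

test_that("r' is continuous in (M, p, q) on the simplex interior", {
  set.seed(21)
  params <- kinetic_params()
  TK <- 305
  f <- function(M, p, q)
    growth_rate(TK, strategy(M, p, q), params)$r_prime
  h <- 1e-6
  for (i in 1:20) {
    s <- random_strategy(M_max = 20)
    base <- f(s$M, s$p, s$q)
    for (d in list(c(h, 0, 0), c(0, h, 0), c(0, 0, h))) {
      step <- f(s$M + d[1], s$p + d[2], s$q + d[3])
      expect_lt(abs(step - base), 1e-3 * max(base, 1e-300) + 1e-300)
    }
  }
})

test_that("with stability ~1, r'(T) is the closed-form Arrhenius curve", {
  # kappa_D -> 0 forces the stability factor to 1 up to 1e-12
  p <- kinetic_params(kappa_D = 1e-14, dH_m = 3e5, T_m = 315)
  s <- strategy(8, 0.3, 0.2)
  Tgrid <- seq(280, 320, by = 1)
  out <- growth_rate(Tgrid, s, p)
  expect_true(all(diff(out$r_prime) > 0))
  const <- juvenile_survival(8, p$c) * productivity(s, p$b)
  closed <- const * arrhenius_rate(p$a_B * s$p * s$M, p$Ea_B, Tgrid)
  expect_equal(out$r_prime, closed, tolerance = 1e-10)
})

test_that("agricultural_impact and relative_response behave", {
  params <- kinetic_params()
  s1 <- strategy(1, 0.3, 0.2)
  expect_equal(agricultural_impact(300, s1, params),
               growth_rate(300, s1, params)$r_prime)
  expect_identical(agricultural_impact(300, strategy(4, 0, 0.2), params), 0)

  expect_equal(relative_response(c(2, 4), 4), c(0.5, 1))
  expect_identical(relative_response(0, 5), 0)
  expect_equal(relative_response(c(3.3, 6.6, 9.9), 3.3), c(1, 2, 3))
  expect_error(relative_response(1, 0), class = "tf_invalid_input")
  expect_error(relative_response(1, -2), class = "tf_invalid_input")
})

test_that("kinetic_params and strategy validate their invariants", {
  expect_error(kinetic_params(c = 1), class = "tf_invalid_input")
  expect_error(kinetic_params(Ea_B = -1), class = "tf_invalid_input")
  expect_error(kinetic_params(T_m = 250), class = "tf_invalid_input")
  expect_error(strategy(-1, 0.2, 0.2), class = "tf_invalid_input")
  expect_error(strategy(1, 0.7, 0.4), class = "tf_invalid_input")
  expect_error(strategy(1, -0.1, 0.2), class = "tf_invalid_input")
})
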