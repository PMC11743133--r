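test_that("overlap_stats matches closed forms and the printed expectation", {
  r <- overlap_stats(10, 10, 100, 1)
  expect_equal(r$expected, 1)
  expect_lt(r$chi2, 1e-12)

  # the published marginals give an independence expectation of 83.40
  paper <- overlap_stats(1269, 765, 11640, 137)
  expect_equal(paper$expected, 83.4007731959, tolerance = 1e-10)
  expect_lt(paper$p_hypergeom, 0.001)

  # frozen brute-force (O-E)^2/E over the four cells
  r5 <- overlap_stats(10, 10, 100, 5)
  expect_equal(r5$chi2, 19.7530864198, tolerance = 1e-10)

  expect_error(overlap_stats(10, 10, 100, 11), class = "tf_invalid_input")
  expect_error(overlap_stats(200, 10, 100, 5), class = "tf_invalid_input")
})

test_that("chi2 equals the standard contingency statistic on random tables", {
  set.seed(51)
  for (i in 1:50) {
    N <- sample(200:5000, 1)
    n_A <- sample(10:(N / 2), 1)
    n_B <- sample(10:(N / 2), 1)
    lo <- max(0, n_A + n_B - N)
    obs <- sample(lo:min(n_A, n_B), 1)
    r <- overlap_stats(n_A, n_B, N, obs)
    # expected overlap equals the hypergeometric mean
    expect_equal(r$expected, n_A * n_B / N, tolerance = 1e-12)
    tab <- matrix(c(obs, n_A - obs, n_B - obs, N - n_A - n_B + obs), 2)
    oracle <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    expect_equal(r$chi2, unname(oracle$statistic), tolerance = 1e-9)
    yates <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(overlap_stats(n_A, n_B, N, obs, correct = TRUE)$chi2,
                 unname(yates$statistic), tolerance = 1e-9)
  }
})

test_that("classify_directions counts quadrants and runs the sign test", {
  p1 <- data.frame(gene_id = "a", lfc_mating = 1, lfc_heat = -1)
  expect_identical(classify_directions(p1)$antagonistic, 1L)
  p2 <- data.frame(gene_id = "a", lfc_mating = 1, lfc_heat = 1)
  expect_identical(classify_directions(p2)$concordant, 1L)

  # zero log-fold changes are excluded with a message
  p3 <- data.frame(gene_id = c("a", "b"), lfc_mating = c(0, 1),
                   lfc_heat = c(1, -2))
  expect_message(r3 <- classify_directions(p3), "excluded 1")
  expect_identical(r3$n_excluded, 1L)
  expect_identical(r3$n, 1L)

  # 134 antagonistic of 137: exact binomial upper tail below 0.001
  p4 <- data.frame(gene_id = sprintf("g%d", 1:137),
                   lfc_mating = c(rep(1, 21), rep(-1, 113), rep(-1, 3)),
                   lfc_heat = c(rep(-1, 21), rep(1, 113), rep(-1, 3)))
  r4 <- classify_directions(p4)
  expect_identical(r4$antagonistic, 134L)
  expect_identical(r4$concordant, 3L)
  expect_identical(unname(r4$quadrants["up_mating_down_heat"]), 21L)
  expect_identical(unname(r4$quadrants["down_mating_up_heat"]), 113L)
  expect_lt(r4$p_binomial, 0.001)
  # oracle: exact summation of the binomial upper tail
  oracle <- sum(choose(137, 134:137)) / 2^137
  expect_equal(r4$p_binomial, oracle, tolerance = 1e-10)
})

test_that("tradeoff_scores are the configured dot products", {
  panel <- data.frame(gene_id = c("g1", "g2"), lfc_mating = c(1, -2),
                      lfc_heat = c(-1, 1))
  counts <- matrix(c(3, 4), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  sc <- tradeoff_scores(panel, counts)
  expect_equal(sc$score_R, -5)
  expect_equal(sc$score_HS, 1)

  zero <- matrix(0, 2, 3, dimnames = list(c("g1", "g2"), NULL))
  sc0 <- tradeoff_scores(panel, zero)
  expect_true(all(sc0$score_R == 0) && all(sc0$score_HS == 0))

  # exact antisymmetry when lfc_heat = -lfc_mating
  anti <- data.frame(gene_id = c("g1", "g2"), lfc_mating = c(1.5, -0.7),
                     lfc_heat = c(-1.5, 0.7))
  set.seed(61)
  cm <- matrix(rpois(20, 50), 2, 10, dimnames = list(c("g1", "g2"), NULL))
  sca <- tradeoff_scores(anti, cm)
  expect_equal(sca$score_HS, -sca$score_R, tolerance = 1e-12)

  bad <- matrix(1, 3, 2)
  expect_error(tradeoff_scores(panel, bad), class = "tf_invalid_input")
  mis <- matrix(1, 2, 2, dimnames = list(c("g2", "g1"), NULL))
  expect_error(tradeoff_scores(panel, mis), class = "tf_invalid_input")
})

test_that("tradeoff_axis_projection recovers collinear clouds and rotations", {
  # points on y = -x: projections reproduce distances along the line
  t_along <- c(-3, -1, 0, 2, 5)
  sc <- data.frame(score_R = t_along / sqrt(2), score_HS = -t_along / sqrt(2))
  pr <- tradeoff_axis_projection(sc)
  expect_equal(pr$correlation, -1, tolerance = 1e-12)
  expect_equal(abs(pr$axis[["score_HS"]]), 1 / sqrt(2), tolerance = 1e-9)
  d <- pr$projection - pr$projection[3]
  expect_equal(abs(d), abs(t_along - t_along[3]), tolerance = 1e-9)
  expect_gte(pr$axis[["score_HS"]], 0)  # maintenance-pole sign convention

  # rotation equivariance of the leading eigenvector
  set.seed(62)
  X <- cbind(stats::rnorm(200, sd = 3), stats::rnorm(200, sd = 1))
  ang <- 0.7
  Rmat <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  pr1 <- tradeoff_axis_projection(data.frame(score_R = X[, 1],
                                             score_HS = X[, 2]))
  Xr <- X %*% t(Rmat)
  pr2 <- tradeoff_axis_projection(data.frame(score_R = Xr[, 1],
                                             score_HS = Xr[, 2]))
  v_rot <- Rmat %*% pr1$axis
  if (v_rot[2] < 0) v_rot <- -v_rot
  expect_equal(unname(pr2$axis), drop(v_rot), tolerance = 1e-6)

  # centering invariance: adding a constant shifts nothing
  pr3 <- tradeoff_axis_projection(data.frame(score_R = X[, 1] + 100,
                                             score_HS = X[, 2] - 42))
  expect_equal(pr3$projection, pr1$projection, tolerance = 1e-8)

  degen <- data.frame(score_R = rep(1, 4), score_HS = rep(2, 4))
  expect_error(tradeoff_axis_projection(degen),
               class = "tf_degenerate_input")
})
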