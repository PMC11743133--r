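#' Optimizer configuration
#'
#' Controls the two-stage search for the optimal strategy: a coarse grid over
#' `M` in `M_bounds` and `(p, q)` on the allocation simplex, followed by
#' derivative-free (Nelder-Mead) refinement from the best grid point.
#'
#' @param M_bounds length-2 positive numeric, lower/upper bound on `M`.
#' @param grid_n points per axis for the coarse grid (>= 5; default 41).
#' @param refine logical, run local refinement after the grid (default TRUE).
#' @param reltol relative convergence tolerance of the refinement
#'   (default 1e-8).
#' @param n_starts number of additional jittered refinement starts (default 2;
#'   0 gives a purely deterministic grid + single polish).
#' @param seed integer seeding the jittered starts.
#' @return an `optimizer_config` object.
#' @export
optimizer_config <- function(M_bounds = c(0.5, 30), grid_n = 41,
                             refine = TRUE, reltol = 1e-8,
                             n_starts = 2, seed = 1L) {
  if (length(M_bounds) != 2 || any(!is.finite(M_bounds)) ||
      M_bounds[1] <= 0 || M_bounds[2] <= M_bounds[1])
    stop_invalid("M_bounds must be positive with low < high")
  if (grid_n < 5) stop_invalid("grid_n must be >= 5")
  structure(list(M_bounds = as.numeric(M_bounds), grid_n = as.integer(grid_n),
                 refine = isTRUE(refine), reltol = reltol,
                 n_starts = as.integer(n_starts), seed = as.integer(seed)),
            class = "optimizer_config")
}

# Simplex-constrained grid of (M, p, q) candidates.
strategy_grid <- function(cfg) {
  M <- seq(cfg$M_bounds[1], cfg$M_bounds[2], length.out = cfg$grid_n)
  a <- seq(0, 1, length.out = cfg$grid_n)
  pq <- expand.grid(p = a, q = a)
  pq <- pq[pq$p + pq$q <= 1, , drop = FALSE]
  g <- expand.grid(M = M, i = seq_len(nrow(pq)))
  data.frame(M = g$M, p = pq$p[g$i], q = pq$q[g$i])
}

# Map unconstrained theta to (M, p, q): M by a logistic squeeze into bounds,
# (p, q) by total allocation s = logistic(theta2) split v = logistic(theta3).
theta_to_strategy <- function(theta, cfg) {
  sig <- function(x) 1 / (1 + exp(-x))
  M <- cfg$M_bounds[1] + (cfg$M_bounds[2] - cfg$M_bounds[1]) * sig(theta[1])
  s <- sig(theta[2]); v <- sig(theta[3])
  c(M = M, p = s * v, q = s * (1 - v))
}

strategy_to_theta <- function(M, p, q, cfg) {
  clamp <- function(x) pmin(pmax(x, 1e-9), 1 - 1e-9)
  logit <- function(x) log(x / (1 - x))
  u <- clamp((M - cfg$M_bounds[1]) / diff(cfg$M_bounds))
  s <- clamp(p + q); v <- clamp(if (p + q > 0) p / (p + q) else 0.5)
  c(logit(u), logit(s), logit(v))
}

#' Find the optimal life-history strategy at a temperature
#'
#' Maximises \eqn{r'(T)} over `M` in `M_bounds`, `p >= 0`, `q >= 0`,
#' `p + q <= 1`. A coarse simplex-constrained grid locates the basin; ties on
#' the grid are broken lexicographically (smallest `M`, then `p`, then `q`);
#' Nelder-Mead refinement (plus optional seeded jittered restarts) polishes
#' the optimum. Deterministic for a fixed config and seed.
#'
#' @param T temperature in Kelvin (scalar).
#' @param params a [kinetic_params()] object.
#' @param cfg an [optimizer_config()] object.
#' @return an `optimal_strategy` list: `strategy`, `r_prime`, `T`,
#'   `converged`, `evaluations`.
#' @export
optimize_strategy <- function(T, params, cfg = optimizer_config()) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(cfg, "optimizer_config"))
  assert_scalar_finite(T, "T")
  if (T <= 0) stop_invalid("T must be > 0 (Kelvin)")

  grid <- strategy_grid(cfg)
  # lexicographic order so which.max picks smallest (M, p, q) among ties
  grid <- grid[order(grid$M, grid$p, grid$q), , drop = FALSE]
  comp <- r_prime_components(T, grid$M, grid$p, grid$q, params)
  r <- comp[, 1] * comp[, 2] * comp[, 3] * comp[, 4]
  n_eval <- nrow(grid)
  best <- which.max(r)

  if (!is.finite(r[best]) || r[best] <= 0) {
    return(structure(list(
      strategy = strategy(cfg$M_bounds[1], 0, 0),
      r_prime = 0, T = T, converged = FALSE, evaluations = n_eval),
      class = "optimal_strategy"))
  }

  M0 <- grid$M[best]; p0 <- grid$p[best]; q0 <- grid$q[best]
  r_best <- r[best]

  if (cfg$refine) {
    obj <- function(theta) {
      s <- theta_to_strategy(theta, cfg)
      comp <- r_prime_components(T, s[["M"]], s[["p"]], s[["q"]], params)
      -(comp[1] * comp[2] * comp[3] * comp[4])
    }
    starts <- list(strategy_to_theta(M0, max(p0, 1e-3), max(q0, 1e-3), cfg))
    if (cfg$n_starts > 0) {
      jit <- with_seed(cfg$seed, replicate(cfg$n_starts,
        starts[[1]] + stats::rnorm(3, sd = 0.5), simplify = FALSE))
      starts <- c(starts, jit)
    }
    for (th0 in starts) {
      fit <- stats::optim(th0, obj, method = "Nelder-Mead",
                          control = list(reltol = cfg$reltol, maxit = 2000))
      # restart from the solution: a fresh simplex escapes premature
      # flat-region termination (matters when M* sits at a bound)
      fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                          control = list(reltol = cfg$reltol, maxit = 2000))
      n_eval <- n_eval + fit$counts[["function"]]
      if (-fit$value > r_best) {
        r_best <- -fit$value
        s <- theta_to_strategy(fit$par, cfg)
        M0 <- s[["M"]]; p0 <- s[["p"]]; q0 <- s[["q"]]
      }
    }
    # coordinate polish on the natural scale: the logistic reparameterisation
    # saturates when the optimum sits on a bound, so finish with 1-D searches
    # that evaluate the exact endpoints
    r1 <- function(M, p, q) {
      comp <- r_prime_components(T, M, p, q, params)
      comp[1] * comp[2] * comp[3] * comp[4]
    }
    for (iter in 1:3) {
      for (coord in c("M", "p", "q")) {
        iv <- switch(coord,
                     M = cfg$M_bounds,
                     p = c(0, 1 - q0),
                     q = c(0, 1 - p0))
        f <- switch(coord,
                    M = function(x) r1(x, p0, q0),
                    p = function(x) r1(M0, x, q0),
                    q = function(x) r1(M0, p0, x))
        op <- stats::optimize(f, iv, maximum = TRUE,
                              tol = 1e-10 * max(1, diff(iv)))
        cand <- c(op$maximum, iv)
        vals <- vapply(cand, f, numeric(1))
        n_eval <- n_eval + length(cand)
        k <- which.max(vals)
        if (vals[k] > r_best) {
          r_best <- vals[k]
          assign(paste0(substr(coord, 1, 1), "0"), cand[k])
        }
      }
    }
  }

  structure(list(strategy = strategy(M0, p0, q0), r_prime = r_best, T = T,
                 converged = TRUE, evaluations = n_eval),
            class = "optimal_strategy")
}

#' @export
print.optimal_strategy <- function(x, ...) {
  cat(sprintf("Optimal strategy at %.2f K (%.2f degC)\n", x$T,
              kelvin_to_celsius(x$T)))
  cat(sprintf("  M* = %.4f  p* = %.4f  q* = %.4f\n",
              x$strategy$M, x$strategy$p, x$strategy$q))
  cat(sprintf("  r' = %.6g  (converged: %s, %d evaluations)\n",
              x$r_prime, x$converged, x$evaluations))
  invisible(x)
}

#' Thermal performance curve of an adapted population
#'
#' Optimises the strategy once at the adaptation temperature `T_adapt`
#' (no plasticity: the adapted population is a single frozen strategy), then
#' evaluates that strategy's growth rate and impact across `T_grid`.
#'
#' @param T_adapt adaptation temperature, Kelvin.
#' @param params a [kinetic_params()] object.
#' @param T_grid increasing vector of evaluation temperatures, Kelvin.
#' @param cfg an [optimizer_config()].
#' @return a data.frame with columns `T`, `r_prime`, `impact`, the four
#'   components, plus attributes `optimum` (the `optimal_strategy`).
#' @export
adapted_performance_curve <- function(T_adapt, params, T_grid,
                                      cfg = optimizer_config()) {
  if (length(T_grid) < 1 || is.unsorted(T_grid, strictly = TRUE))
    stop_invalid("T_grid must be non-empty and strictly increasing")
  opt <- optimize_strategy(T_adapt, params, cfg)
  curve <- growth_rate(T_grid, opt$strategy, params)
  attr(curve, "optimum") <- opt
  curve
}

#' Thermal niche breadth of a performance curve
#'
#' Total temperature span over which `r'` is at least `level` times the curve
#' maximum, with linear interpolation at the threshold crossings. A curve
#' that is identically zero has breadth 0 (with a warning).
#'
#' @param curve data.frame with columns `T` and `r_prime` (as returned by
#'   [adapted_performance_curve()]), at least 3 points.
#' @param level threshold fraction of the maximum, in (0, 1); default 0.5.
#' @return breadth in Kelvin (= span in degrees Celsius).
#' @export
niche_breadth <- function(curve, level = 0.5) {
  if (!all(c("T", "r_prime") %in% names(curve)) || nrow(curve) < 3)
    stop_invalid("curve must have columns T, r_prime and >= 3 points")
  if (level <= 0 || level >= 1) stop_invalid("level must be in (0, 1)")
  x <- curve$T; y <- curve$r_prime
  ymax <- max(y)
  if (ymax <= 0) {
    warning("flat-zero performance curve: breadth is 0")
    return(0)
  }
  thr <- level * ymax
  above <- y >= thr
  width <- 0
  for (i in seq_len(length(x) - 1)) {
    x1 <- x[i]; x2 <- x[i + 1]; y1 <- y[i]; y2 <- y[i + 1]
    if (above[i] && above[i + 1]) {
      width <- width + (x2 - x1)
    } else if (xor(above[i], above[i + 1])) {
      xc <- x1 + (thr - y1) / (y2 - y1) * (x2 - x1)
      width <- width + if (above[i]) xc - x1 else x2 - xc
    }
  }
  width
}

#' Temperatures of peak growth rate and peak impact
#'
#' For each grid temperature the strategy is re-optimised (populations adapt
#' locally), and the grid argmax temperatures of the resulting `r'` and
#' impact (`M* r'`) curves are returned. Because hotter optima favour larger
#' `M`, the impact peak sits at or above the growth-rate peak.
#'
#' @param params a [kinetic_params()] object.
#' @param T_grid increasing vector of temperatures, Kelvin, spanning both
#'   peaks.
#' @param cfg an [optimizer_config()].
#' @return a list with `T_at_max_r`, `T_at_max_impact`, the per-temperature
#'   data.frame `curve`, and `boundary` (TRUE if either peak lies on the grid
#'   boundary, with a warning).
#' @export
impact_peak_displacement <- function(params, T_grid, cfg = optimizer_config()) {
  if (length(T_grid) < 3 || is.unsorted(T_grid, strictly = TRUE))
    stop_invalid("T_grid must be strictly increasing with >= 3 points")
  opts <- lapply(T_grid, optimize_strategy, params = params, cfg = cfg)
  r <- vapply(opts, `[[`, numeric(1), "r_prime")
  M <- vapply(opts, function(o) o$strategy$M, numeric(1))
  impact <- M * r
  i_r <- which.max(r); i_imp <- which.max(impact)
  boundary <- i_r %in% c(1L, length(T_grid)) ||
    i_imp %in% c(1L, length(T_grid))
  if (boundary) warning("a peak lies on the temperature-grid boundary")
  list(T_at_max_r = T_grid[i_r], T_at_max_impact = T_grid[i_imp],
       curve = data.frame(T = T_grid, r_prime = r, M_opt = M,
                          impact = impact),
       boundary = boundary)
}
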