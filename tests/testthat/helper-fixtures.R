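# Shared fixtures: a light optimizer config for unit tests (the acceptance
# suite uses the full-resolution oracle) and a random-parameter draw.

fast_cfg <- function(grid_n = 21, n_starts = 0, seed = 1L)
  optimizer_config(grid_n = grid_n, n_starts = n_starts, seed = seed)

random_params <- function() {
  kinetic_params(
    a_B = 1,
    Ea_B = stats::runif(1, 40000, 90000),
    kappa_D = stats::runif(1, 0.5, 20),
    dH_m = stats::runif(1, 1.5e5, 5e5),
    T_m = stats::runif(1, 300, 330),
    dCp = 0,
    c = stats::runif(1, 0.02, 0.3),
    b = stats::runif(1, 0.5, 1))
}

random_strategy <- function(M_max = 30) {
  p <- stats::runif(1, 0.01, 0.9)
  q <- stats::runif(1, 0.01, 1 - p - 0.01)
  strategy(stats::runif(1, 0.5, M_max), p, q)
}

# Brute-force maximum of r' over a dense simplex-constrained grid;
# the independent oracle for the optimizer (vectorised, no optim involved).
dense_grid_max <- function(T, params, M_bounds, n = 201) {
  M <- seq(M_bounds[1], M_bounds[2], length.out = n)
  a <- seq(0, 1, length.out = n)
  pq <- expand.grid(p = a, q = a)
  pq <- pq[pq$p + pq$q <= 1, ]
  best <- 0
  for (m in M) {
    r <- thermofoot:::r_prime_components(T, m, pq$p, pq$q, params)
    best <- max(best, max(r[, 1] * r[, 2] * r[, 3] * r[, 4]))
  }
  best
}
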