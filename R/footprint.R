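#' Agricultural footprint, metric 1
#'
#' `phi1 = C_m * omega * mass_M / d1`: host mass destroyed per day implied by
#' a female's lifetime offspring production `omega`, adult body mass at
#' emergence `mass_M` (mg), egg-to-adult development time `d1` (days), and the
#' temperature-specific conversion constant `C_m` (mg host consumed per mg
#' beetle produced, see [estimate_Cm()]).
#'
#' @param C_m conversion constant, mg host per mg beetle (>= 0).
#' @param omega lifetime adult offspring per female (>= 0).
#' @param mass_M adult female body mass at emergence, mg (>= 0).
#' @param d1 mean egg-to-adult development time, days (> 0).
#' @return footprint in mg host per day; vectorised over its arguments.
#' @export
phi1 <- function(C_m, omega, mass_M, d1) {
  if (any(!is.finite(d1)) || any(d1 <= 0)) stop_invalid("d1 must be > 0")
  if (any(C_m < 0) || any(omega < 0) || any(mass_M < 0))
    stop_invalid("C_m, omega and mass_M must be >= 0")
  C_m * omega * mass_M / d1
}

#' Agricultural footprint, metric 2
#'
#' `phi2 = psi * C_E / d2`: an independent footprint estimate from early
#' fecundity `psi` (eggs in the first 16 h), per-egg host consumption `C_E`
#' (mg host per egg, see [estimate_CE()]), and the development time `d2` of
#' the fastest individual per dish (days).
#'
#' @param psi eggs laid per female in the first 16 h (>= 0).
#' @param C_E host mass consumed per laid egg, mg (>= 0).
#' @param d2 development time of the fastest individual, days (> 0).
#' @return footprint in mg host per day.
#' @export
phi2 <- function(psi, C_E, d2) {
  if (any(!is.finite(d2)) || any(d2 <= 0)) stop_invalid("d2 must be > 0")
  if (any(psi < 0) || any(C_E < 0)) stop_invalid("psi and C_E must be >= 0")
  psi * C_E / d2
}

#' Footprint change relative to the ancestor at 29 degrees C
#'
#' `100 * (line_phi / ancestor_phi_29C - 1)`: percent change of a line's
#' footprint relative to its own geographic ancestor reared at the benign
#' temperature. The reference is always the line's respective ancestor, never
#' a pooled one.
#'
#' @param line_phi footprint(s) of the focal line(s).
#' @param ancestor_phi_29C footprint of the respective ancestor at 29 C (> 0).
#' @return percent change(s).
#' @export
relative_footprint <- function(line_phi, ancestor_phi_29C) {
  if (any(!is.finite(ancestor_phi_29C)) || any(ancestor_phi_29C <= 0))
    stop_invalid("ancestor footprint must be > 0")
  100 * (line_phi / ancestor_phi_29C - 1)
}

#' Parametric bootstrap of the phi1 footprint
#'
#' Propagates trait estimation error into the footprint: each trait is drawn
#' independently from Normal(mean, se) (truncated below at 1e-6 of its mean
#' for the strictly positive traits `mass_M` and `d1`; truncation events are
#' counted), `phi1` is recomputed per draw, and percentile 2.5/97.5 bounds
#' are returned. The point estimate is the noise-free plug-in value from the
#' trait means.
#'
#' @param traits a list/row with elements `omega`, `mass_M`, `d1`, each a
#'   list with `mean` and `se` (se >= 0).
#' @param C_m conversion constant (treated as fixed).
#' @param n_boot number of bootstrap draws (>= 1).
#' @param seed integer seed; identical seeds give identical intervals.
#' @return a `footprint_result` list: `phi`, `ci_low`, `ci_high`, `n_boot`,
#'   `seed`, `n_truncated`.
#' @export
parametric_bootstrap <- function(traits, C_m, n_boot = 10000, seed = 1L) {
  need <- c("omega", "mass_M", "d1")
  if (!all(need %in% names(traits)))
    stop_invalid("traits must contain omega, mass_M, d1")
  for (nm in need) {
    tr <- traits[[nm]]
    if (!all(c("mean", "se") %in% names(tr)) || !is.finite(tr$mean) ||
        !is.finite(tr$se) || tr$se < 0)
      stop_invalid(sprintf("trait '%s' needs finite mean and se >= 0", nm))
  }
  if (n_boot < 1) stop_invalid("n_boot must be >= 1")
  phi_hat <- phi1(C_m, traits$omega$mean, traits$mass_M$mean, traits$d1$mean)
  n_trunc <- 0L
  draws <- with_seed(seed, {
    om <- stats::rnorm(n_boot, traits$omega$mean, traits$omega$se)
    ms <- stats::rnorm(n_boot, traits$mass_M$mean, traits$mass_M$se)
    dv <- stats::rnorm(n_boot, traits$d1$mean, traits$d1$se)
    om <- pmax(om, 0)
    floor_ms <- 1e-6 * abs(traits$mass_M$mean)
    floor_dv <- 1e-6 * abs(traits$d1$mean)
    n_trunc <- sum(ms < floor_ms) + sum(dv < floor_dv)
    ms <- pmax(ms, floor_ms); dv <- pmax(dv, floor_dv)
    C_m * om * ms / dv
  })
  ci <- unname(stats::quantile(draws, c(0.025, 0.975), type = 7))
  structure(list(phi = phi_hat, ci_low = ci[1], ci_high = ci[2],
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 n_truncated = n_trunc),
            class = "footprint_result")
}

#' Per-generation rate of footprint change
#'
#' Divides a total percent change by the number of generations elapsed,
#' assuming trait evolution proceeded at a constant (linear) pace; reported
#' to one decimal, matching conventional reporting.
#'
#' @param delta_pct total percent change.
#' @param n_generations generations elapsed (>= 1).
#' @return percent change per generation, rounded to one decimal.
#' @export
per_generation_rate <- function(delta_pct, n_generations) {
  if (any(n_generations < 1)) stop_invalid("n_generations must be >= 1")
  round(delta_pct / n_generations, 1)
}

#' Correlation between the two footprint metrics
#'
#' Pearson correlation of per-line `phi1` and `phi2` values, with the
#' t statistic `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param phi1_by_line,phi2_by_line equal-length numeric vectors (n >= 3).
#' @return a list with `r`, `t`, `df`.
#' @export
footprint_correlation <- function(phi1_by_line, phi2_by_line) {
  n <- length(phi1_by_line)
  if (length(phi2_by_line) != n || n < 3)
    stop_invalid("inputs must be equal length with n >= 3")
  if (stats::sd(phi1_by_line) == 0 || stats::sd(phi2_by_line) == 0)
    stop_degenerate("zero variance: correlation undefined")
  r <- stats::cor(phi1_by_line, phi2_by_line)
  df <- n - 2L
  list(r = r, t = r * sqrt(df / (1 - r^2)), df = df)
}

#' Selection differential on a trait
#'
#' `S = cov(w / mean(w), z)` with an `n - 1` denominator, where `w` is
#' fitness and `z` the z-scored trait: the classical directional selection
#' differential in units of trait standard deviations.
#'
#' @param fitness numeric vector of fitness values (mean > 0).
#' @param trait numeric vector, same length (variance > 0), n >= 3.
#' @return the selection differential `S`.
#' @export
selection_differential <- function(fitness, trait) {
  n <- length(fitness)
  if (length(trait) != n || n < 3)
    stop_invalid("fitness and trait must be equal length, n >= 3")
  if (mean(fitness) <= 0) stop_degenerate("mean fitness must be > 0")
  if (stats::sd(trait) == 0) stop_degenerate("trait variance must be > 0")
  w_rel <- fitness / mean(fitness)
  z <- (trait - mean(trait)) / stats::sd(trait)
  stats::cov(w_rel, z)
}
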