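#' Universal gas constant (J / (mol K))
#' @export
R_GAS <- 8.314

#' Kinetic parameters of the thermodynamic life-history model
#'
#' Bundles the constants governing temperature-dependent productivity and
#' failure. Productivity follows Arrhenius kinetics with activation energy
#' `Ea_B` and a rate scale proportional to the catalytic allocation `p * M`
#' (scale constant `a_B`). Failure is modelled through reversible two-state
#' protein unfolding: the unfolding equilibrium constant
#' \eqn{K_u(T) = \exp(-\Delta G_u(T) / (R T))} with
#' \eqn{\Delta G_u(T) = \Delta H_m (1 - T/T_m) - \Delta C_p [(T_m - T) + T \log(T/T_m)]}
#' enters the mortality term with scale `kappa_D / (q * M)`, so maintenance
#' allocation `q * M` buys protein stability. Proportionality constants of the
#' underlying rate laws are absorbed into `a_B` and `kappa_D`; outputs are in
#' relative units.
#'
#' @param a_B productivity rate scale per unit `p * M` (dimensionless).
#' @param Ea_B productivity activation energy, J/mol (> 0).
#' @param kappa_D failure scale before division by `q * M` (> 0).
#' @param dH_m enthalpy of unfolding at the midpoint, J/mol (> 0).
#' @param T_m unfolding midpoint temperature, K (> 273.15).
#' @param dCp heat-capacity change of unfolding, J/(mol K); default 0 (no
#'   curvature in \eqn{\Delta G_u}).
#' @param c per-unit cost of juvenile resource acquisition, a probability in
#'   `[0, 1)`: survival to maturity is `(1 - c)^M`.
#' @param b allometric exponent of productivity (default 0.75).
#' @return an object of class `kinetic_params` (a validated list).
#' @seealso [growth_rate()], [optimize_strategy()], [default_params()]
#' @export
kinetic_params <- function(a_B = 1, Ea_B = 65000, kappa_D = 5,
                           dH_m = 3e5, T_m = 315, dCp = 0,
                           c = 0.1, b = 0.75) {
  for (nm in c("a_B", "Ea_B", "kappa_D", "dH_m", "T_m", "dCp", "c", "b"))
    assert_scalar_finite(get(nm), nm)
  if (Ea_B <= 0) stop_invalid("Ea_B must be > 0")
  if (kappa_D <= 0) stop_invalid("kappa_D must be > 0")
  if (dH_m <= 0) stop_invalid("dH_m must be > 0")
  if (T_m <= 273.15) stop_invalid("T_m must exceed 273.15 K")
  if (c < 0 || c >= 1) stop_invalid("c must satisfy 0 <= c < 1")
  if (b <= 0 || b > 1) stop_invalid("b must satisfy 0 < b <= 1")
  if (a_B < 0) stop_invalid("a_B must be >= 0")
  structure(list(a_B = a_B, Ea_B = Ea_B, kappa_D = kappa_D, dH_m = dH_m,
                 T_m = T_m, dCp = dCp, c = c, b = b, R_gas = R_GAS),
            class = "kinetic_params")
}

#' Default kinetic parameter set
#'
#' Reads the parameter values shipped in `inst/extdata/default_config.json`.
#' These defaults were chosen so that the optimal-strategy model reproduces
#' the expected qualitative behaviours (hot adaptation favours larger M and
#' larger q; cheaper feeding widens the thermal niche; the impact peak sits
#' at or above the growth-rate peak).
#'
#' @return a `kinetic_params` object.
#' @export
default_params <- function() {
  cfg <- read_run_config(system.file("extdata", "default_config.json",
                                     package = "thermofoot"))
  cfg$model
}

#' A life-history strategy (M, p, q)
#'
#' @param M acquired energy reserves (> 0, relative units).
#' @param p fraction of `M` allocated to catalytic capacity (>= 0).
#' @param q fraction of `M` allocated to maintenance/chaperones (>= 0).
#'   `p + q` must not exceed 1; the residual `M (1 - p - q)` funds growth and
#'   reproduction.
#' @return an object of class `strategy`.
#' @export
strategy <- function(M, p, q) {
  assert_scalar_finite(M, "M"); assert_scalar_finite(p, "p")
  assert_scalar_finite(q, "q")
  if (M <= 0) stop_invalid("M must be > 0")
  if (p < 0 || q < 0) stop_invalid("p and q must be >= 0")
  if (p + q > 1 + 1e-12) stop_invalid("p + q must not exceed 1")
  structure(list(M = M, p = p, q = q), class = "strategy")
}

#' @export
format.strategy <- function(x, ...)
  sprintf("<strategy M=%.6g p=%.6g q=%.6g>", x$M, x$p, x$q)

#' @export
print.strategy <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Arrhenius rate law
#'
#' `A * exp(-Ea / (R T))`: the canonical temperature scaling of
#' reaction-like biological rates.
#'
#' @param A rate scale (>= 0).
#' @param Ea activation energy, J/mol.
#' @param T temperature in Kelvin (> 0); vectorised.
#' @return rate(s), same length as `T`.
#' @examples
#' arrhenius_rate(1, 0, 300)        # 1
#' arrhenius_rate(1, 60000, 298.15) # ~3.06e-11
#' @export
arrhenius_rate <- function(A, Ea, T) {
  if (!is.numeric(T) || any(!is.finite(T)) || any(T <= 0))
    stop_invalid("T must be positive and finite (Kelvin)")
  if (!is.numeric(A) || any(A < 0)) stop_invalid("A must be >= 0")
  if (!is.numeric(Ea) || any(!is.finite(Ea))) stop_invalid("Ea must be finite")
  A * exp(-Ea / (R_GAS * T))
}

#' Two-state protein-unfolding equilibrium constant
#'
#' \eqn{K_u(T) = \exp(-\Delta G_u(T)/(R T))} with
#' \eqn{\Delta G_u(T) = \Delta H_m (1 - T/T_m) - \Delta C_p [(T_m - T) + T \log(T/T_m)]}.
#' At the midpoint `T = T_m`, \eqn{\Delta G_u = 0} and `K_u = 1` exactly.
#'
#' @param T temperature in Kelvin (> 0); vectorised.
#' @param params a [kinetic_params()] object.
#' @return equilibrium constant(s) `K_u(T)` (> 0).
#' @export
unfold_constant <- function(T, params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.numeric(T) || any(!is.finite(T)) || any(T <= 0))
    stop_invalid("T must be positive and finite (Kelvin)")
  dG <- params$dH_m * (1 - T / params$T_m) -
    params$dCp * ((params$T_m - T) + T * log(T / params$T_m))
  exp(-dG / (R_GAS * T))
}

#' Proportion of properly folded protein (stability factor)
#'
#' `1 / (1 + (kappa_D / (q M)) K_u(T))`: the fraction of the catalytic
#' machinery that remains folded, given maintenance investment `q * M`.
#' Strictly increasing in `q * M`; `q = 0` returns 0 (the documented limit,
#' not an error, so optimisers can probe the boundary).
#'
#' @inheritParams unfold_constant
#' @param s a [strategy()] object.
#' @return stability fraction(s) in `[0, 1)`.
#' @export
stability_factor <- function(T, s, params) {
  stopifnot(inherits(s, "strategy"))
  if (s$q <= 0) return(rep(0, length(T)))
  Ku <- unfold_constant(T, params)
  1 / (1 + (params$kappa_D / (s$q * s$M)) * Ku)
}

#' Juvenile survival to maturity
#'
#' `(1 - c)^M`: each unit of resource acquired as a larva costs a fixed
#' mortality probability `c`, so survival declines geometrically in `M`.
#'
#' @param M acquired reserves (>= 0); vectorised.
#' @param c per-unit acquisition cost in `[0, 1)`.
#' @return survival probability/probabilities.
#' @export
juvenile_survival <- function(M, c) {
  if (!is.numeric(c) || any(c < 0) || any(c >= 1))
    stop_invalid("c must satisfy 0 <= c < 1")
  if (!is.numeric(M) || any(M < 0)) stop_invalid("M must be >= 0")
  (1 - c)^M
}

#' Productivity from residual reserves
#'
#' `[M (1 - p - q)]^b`: reserves not spent on catalysis or maintenance fund
#' growth and reproduction, with allometric exponent `b`.
#'
#' @param s a [strategy()] object.
#' @param b allometric exponent (default 0.75).
#' @return productivity `B` (>= 0).
#' @export
productivity <- function(s, b = 0.75) {
  stopifnot(inherits(s, "strategy"))
  resid <- s$M * max(0, 1 - s$p - s$q)
  resid^b
}

# Fully vectorised r' over aligned vectors (used by grids and the optimizer
# oracle); returns the component matrix. T in Kelvin.
r_prime_components <- function(T, M, p, q, params) {
  surv <- (1 - params$c)^M
  resid <- pmax(0, M * (1 - p - q))
  B <- resid^params$b
  rr <- params$a_B * p * M * exp(-params$Ea_B / (R_GAS * T))
  dG <- params$dH_m * (1 - T / params$T_m) -
    params$dCp * ((params$T_m - T) + T * log(T / params$T_m))
  Ku <- exp(-dG / (R_GAS * T))
  # kappa_D/(q M) -> Inf at q = 0 gives stab = 0, but guard the Ku-underflow
  # NaN explicitly
  stab <- 1 / (1 + (params$kappa_D / (q * M)) * Ku)
  if (any(q <= 0)) stab[rep_len(q <= 0, length(stab))] <- 0
  cbind(survival = surv, productivity = B, reaction_rate = rr,
        stability = stab)
}

#' Population growth rate and its components
#'
#' Evaluates \eqn{r'(T)} as the product of four factors: juvenile survival
#' `(1-c)^M`, productivity `[M(1-p-q)]^b`, the Arrhenius reaction-rate term
#' `a_B p M exp(-Ea_B/(R T))`, and the protein-stability factor.
#' `r'` is 0 whenever `p = 0`, `q = 0` or `p + q = 1`.
#'
#' @param T temperature(s) in Kelvin.
#' @param s a [strategy()] object.
#' @param params a [kinetic_params()] object.
#' @return a data.frame with one row per temperature and columns `T`,
#'   `r_prime`, `impact` (`M * r_prime`), `survival`, `productivity`,
#'   `reaction_rate`, `stability`.
#' @export
growth_rate <- function(T, s, params) {
  stopifnot(inherits(s, "strategy"), inherits(params, "kinetic_params"))
  if (!is.numeric(T) || any(!is.finite(T)) || any(T <= 0))
    stop_invalid("T must be positive and finite (Kelvin)")
  comp <- r_prime_components(T, s$M, s$p, s$q, params)
  r <- comp[, 1] * comp[, 2] * comp[, 3] * comp[, 4]
  data.frame(T = T, r_prime = r, impact = s$M * r,
             survival = comp[, "survival"],
             productivity = comp[, "productivity"],
             reaction_rate = comp[, "reaction_rate"],
             stability = comp[, "stability"],
             row.names = NULL)
}

#' Agricultural impact of a strategy
#'
#' The product `M * r'(T)`: per-capita host consumption is assumed
#' proportional to acquired reserves `M`, so impact scales growth rate by
#' acquisition.
#'
#' @inheritParams growth_rate
#' @return numeric vector of impacts, one per temperature.
#' @export
agricultural_impact <- function(T, s, params) {
  growth_rate(T, s, params)$impact
}

#' Scale a response relative to a reference value
#'
#' Element-wise division by a positive reference, e.g. the ancestor maximum,
#' so curves can be compared on a relative axis.
#'
#' @param values numeric vector.
#' @param reference positive scalar.
#' @return `values / reference`.
#' @export
relative_response <- function(values, reference) {
  assert_scalar_finite(reference, "reference")
  if (reference <= 0) stop_invalid("reference must be > 0")
  values / reference
}
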