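#' Correct host-mass loss for beetle-free control drift
#'
#' Subtracts the temperature-matched mean control loss (evaporation and
#' handling drift, typically 1-2% of bean weight) from every dish's raw host
#' loss. Negative corrected values are floored at 0; the number of floored
#' dishes is recorded in attribute `n_floored`.
#'
#' @param assays data.frame of consumption assays with at least
#'   `assay_temp_C` and `host_loss_raw` (mg).
#' @param controls data.frame of beetle-free controls with `assay_temp_C` and
#'   `host_loss` (mg); every assay temperature must be represented.
#' @return `assays` with an added `host_loss_corrected` column.
#' @export
control_correct <- function(assays, controls) {
  if (!all(c("assay_temp_C", "host_loss_raw") %in% names(assays)))
    stop_schema("assays need columns assay_temp_C, host_loss_raw")
  if (!all(c("assay_temp_C", "host_loss") %in% names(controls)))
    stop_schema("controls need columns assay_temp_C, host_loss")
  missing_T <- setdiff(unique(assays$assay_temp_C),
                       unique(controls$assay_temp_C))
  if (length(missing_T) > 0)
    stop_config(sprintf("no control assays at temperature(s): %s",
                        paste(missing_T, collapse = ", ")))
  ctrl_mean <- tapply(controls$host_loss, controls$assay_temp_C, mean)
  corr <- assays$host_loss_raw -
    as.vector(ctrl_mean[as.character(assays$assay_temp_C)])
  n_floored <- sum(corr < 0)
  assays$host_loss_corrected <- pmax(corr, 0)
  attr(assays, "n_floored") <- n_floored
  assays
}

#' Cumulative beetle mass produced in a dish
#'
#' `survivors * mean_adult_mass` (mg): the biomass of beetles a dish yielded,
#' the predictor of host consumption used by the conversion-constant fit.
#'
#' @param assay data.frame with `survivors` and `mean_adult_mass` columns
#'   (or a single-row list).
#' @return numeric vector, mg of beetle produced.
#' @export
beetle_mass_produced <- function(assay) {
  if (!all(c("survivors", "mean_adult_mass") %in% names(assay)))
    stop_schema("assay needs columns survivors, mean_adult_mass")
  assay$survivors * assay$mean_adult_mass
}

#' Estimate the mass-conversion constant C_m at one temperature
#'
#' Least-squares slope of corrected host loss on beetle mass produced.
#' The default regresses through the origin (a dish producing no beetle mass
#' consumes essentially nothing); `intercept = TRUE` fits an ordinary
#' intercept model and returns its slope instead.
#'
#' @param assays data.frame of dishes at a single temperature with columns
#'   `survivors`, `mean_adult_mass`, `host_loss_corrected`; at least 3 dishes
#'   with positive beetle mass.
#' @param intercept logical, include an intercept (default FALSE).
#' @return a list with `C_m` (slope, mg host per mg beetle), `se`, `n`.
#' @export
estimate_Cm <- function(assays, intercept = FALSE) {
  x <- beetle_mass_produced(assays)
  y <- assays$host_loss_corrected
  if (is.null(y)) stop_schema("assays need column host_loss_corrected")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (sum(x > 0) < 3) stop_invalid("need >= 3 dishes with positive beetle mass")
  if (all(x == 0)) stop_degenerate("all-zero predictor: slope undefined")
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ 0 + x)
  co <- summary(fit)$coefficients
  list(C_m = unname(co["x", "Estimate"]), se = unname(co["x", "Std. Error"]),
       n = length(x))
}

#' Estimate the per-egg consumption constant C_E
#'
#' Pooled ratio estimator `sum(host_loss_corrected) / sum(eggs)` over dishes,
#' robust to low-egg dishes. Applied per temperature when `by_temp = TRUE`.
#'
#' @param assays data.frame with columns `eggs`, `host_loss_corrected` (and
#'   `assay_temp_C` if `by_temp`).
#' @param by_temp logical, estimate per assay temperature (default FALSE).
#' @return scalar `C_E` (mg host per egg), or a named vector per temperature.
#' @export
estimate_CE <- function(assays, by_temp = FALSE) {
  if (!all(c("eggs", "host_loss_corrected") %in% names(assays)))
    stop_schema("assays need columns eggs, host_loss_corrected")
  ratio <- function(d) {
    tot <- sum(d$eggs)
    if (tot <= 0) stop_degenerate("zero total eggs: C_E undefined")
    sum(d$host_loss_corrected) / tot
  }
  if (!by_temp) return(ratio(assays))
  vapply(split(assays, assays$assay_temp_C), ratio, numeric(1))
}

#' Variance in host consumption explained by life-history traits
#'
#' Ordinary least squares of corrected host loss on nested predictor sets:
#' (1) eggs laid; (2) eggs + survivors; (3) eggs + survivors + mean adult
#' mass (main effects only). Returns the three R-squared values, which are
#' non-decreasing by construction.
#'
#' @param assays data.frame with columns `eggs`, `survivors`,
#'   `mean_adult_mass`, `host_loss_corrected`; at least 10 dishes.
#' @return named numeric vector `c(eggs=, eggs_survivors=, full=)` of R^2.
#' @export
lifehistory_variance_explained <- function(assays) {
  need <- c("eggs", "survivors", "mean_adult_mass", "host_loss_corrected")
  if (!all(need %in% names(assays)))
    stop_schema(sprintf("assays need columns: %s", paste(need, collapse = ", ")))
  if (nrow(assays) < 10) stop_invalid("need >= 10 dishes")
  forms <- list(
    eggs = host_loss_corrected ~ eggs,
    eggs_survivors = host_loss_corrected ~ eggs + survivors,
    full = host_loss_corrected ~ eggs + survivors + mean_adult_mass)
  r2 <- vapply(forms, function(f) {
    fit <- stats::lm(f, data = assays)
    if (any(is.na(stats::coef(fit))))
      stop_degenerate("rank-deficient design in variance decomposition")
    summary(fit)$r.squared
  }, numeric(1))
  r2
}
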