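#' Experimental-evolution design specification
#'
#' The default mirrors a three-origin experimental-evolution design: for each
#' geographic origin, two replicate lines per thermal selection regime (cold,
#' adapted at 23 C; hot, adapted at 35 C) plus the origin's ancestor kept at
#' 29 C, every line assayed in a common garden at 23, 29 and 35 C.
#'
#' @param origins character vector of origin labels (default three).
#' @param replicates_per_regime replicate lines per origin x regime
#'   (default 2).
#' @param assay_temps_C assay temperatures in Celsius (default 23, 29, 35).
#' @param seed integer master seed for all generators using this design.
#' @return a `design_spec` object; `lines(design)`-style table in `$lines`.
#' @export
design_spec <- function(origins = c("Brazil", "California", "Yemen"),
                        replicates_per_regime = 2,
                        assay_temps_C = c(23, 29, 35),
                        seed = 1L) {
  if (length(origins) < 1) stop_invalid("need at least one origin")
  if (replicates_per_regime < 1) stop_invalid("replicates_per_regime >= 1")
  regimes <- c("cold", "hot")
  lines <- do.call(rbind, lapply(origins, function(o) {
    evolved <- expand.grid(rep = seq_len(replicates_per_regime),
                           regime = regimes, stringsAsFactors = FALSE)
    rbind(
      data.frame(line_id = sprintf("%s_%s_%d", substr(o, 1, 3),
                                   evolved$regime, evolved$rep),
                 origin = o, regime = evolved$regime),
      data.frame(line_id = sprintf("%s_anc", substr(o, 1, 3)),
                 origin = o, regime = "ancestor"))
  }))
  structure(list(origins = origins,
                 replicates_per_regime = as.integer(replicates_per_regime),
                 regimes = c(regimes, "ancestor"),
                 assay_temps_C = assay_temps_C,
                 seed = as.integer(seed),
                 lines = lines),
            class = "design_spec")
}

#' Effect-structure specification for the synthetic generators
#'
#' All generator parameters live here, not in code. Baseline trait means are
#' chosen so the ancestral footprint `omega * mass / d1` is flat across assay
#' temperatures (no plasticity in the footprint by default), so the
#' configured regime multipliers map directly onto ancestor-relative
#' footprint changes: the default hot-regime bundle at 35 C multiplies
#' `omega * mass / d1` by 1.8 (a +80% footprint) and the cold bundle at 23 C
#' by 1.076 (+7.6%). Consumption uses the temperature-specific conversion
#' constants `C_m` = 3.17 / 3.66 / 3.55 mg host per mg beetle at 23/29/35 C.
#'
#' @param baseline named list of per-temperature trait means, each a vector
#'   aligned with `assay_temps_C`: `omega`, `mass_M` (mg), `d1` (days),
#'   `psi`, `d2` (days).
#' @param regime_effects named list `regime$trait` of per-temperature
#'   multipliers.
#' @param origin_scale named multiplicative origin offsets applied to the
#'   reproductive traits.
#' @param trait_cv relative SE (and between-line noise) of every trait mean.
#' @param line_scale_sd SD of the lognormal line-level scaling shared by
#'   `omega` and `psi` (creates correlation between the two footprint
#'   metrics).
#' @param C_m named/numeric vector of conversion constants per assay
#'   temperature (mg host per mg beetle).
#' @param C_E per-egg host consumption used by the phi2 pipeline (mg/egg).
#' @param eggs_lambda Poisson mean of hatched eggs per dish.
#' @param eggs_sd_log log-normal SD of the per-dish fecundity rate (dish
#'   heterogeneity: females differ and some dishes nearly fail, so dishes
#'   span a wide beetle-mass range as real assays do).
#' @param surv_p egg-to-pupa survival probability per dish.
#' @param residual_cv dish-level residual noise: the Gaussian SD equals
#'   `residual_cv` times the mean expected consumption at that temperature.
#' @param control_drift,control_sd mean and SD (mg) of beetle-free control
#'   host-mass drift.
#' @param n_antag_up_R,n_antag_up_HS,n_concordant panel quadrant sizes:
#'   up-in-mating/down-in-heat, down-in-mating/up-in-heat, concordant
#'   (both down). Defaults 21 / 113 / 3.
#' @param mirror_sd lognormal SD of the antagonistic mirroring
#'   (`lfc_heat = -lfc_mating * exp(N(0, mirror_sd))`); 0 gives exact
#'   antisymmetry.
#' @param shift35 log-scale expression shift of 35 C samples along the
#'   heat-response direction (maintenance pole).
#' @param nb_dispersion negative-binomial dispersion of counts
#'   (variance = mu + dispersion * mu^2).
#' @return an `effect_spec` object (a validated list).
#' @export
effect_spec <- function(
    baseline = list(omega = c(60, 60, 60),
                    mass_M = c(6.6, 6.0, 5.5),
                    d1 = c(26.4, 24.0, 22.0),
                    psi = c(40, 40, 40),
                    d2 = c(23.76, 21.6, 19.8)),
    regime_effects = list(
      hot = list(omega = c(1, 1.15, 1.40),
                 mass_M = c(1, 1.05, 1.20),
                 d1 = c(1, 1.00, 1.68 / 1.8),
                 psi = c(1, 1.10, 1.50),
                 d2 = c(1, 1.00, 1 / 1.20)),
      cold = list(omega = c(1.04, 1, 1),
                  mass_M = c(1.02, 1, 1),
                  d1 = c(1.0608 / 1.076, 1, 1),
                  psi = c(1.05, 1, 1),
                  d2 = c(1.05 / 1.076, 1, 1)),
      ancestor = list(omega = c(1, 1, 1), mass_M = c(1, 1, 1),
                      d1 = c(1, 1, 1), psi = c(1, 1, 1), d2 = c(1, 1, 1))),
    origin_scale = c(Brazil = 1, California = 1.05, Yemen = 0.95),
    trait_cv = 0.05,
    line_scale_sd = 0.08,
    C_m = c(`23` = 3.17, `29` = 3.66, `35` = 3.55),
    C_E = 15,
    eggs_lambda = 60,
    eggs_sd_log = 0.4,
    surv_p = 0.85,
    residual_cv = 0.05,
    control_drift = 8,
    control_sd = 2,
    n_antag_up_R = 21,
    n_antag_up_HS = 113,
    n_concordant = 3,
    mirror_sd = 0.15,
    shift35 = 0.5,
    nb_dispersion = 0.05) {
  stopifnot(all(vapply(baseline, function(x) all(x > 0), logical(1))))
  if (trait_cv < 0 || residual_cv < 0) stop_invalid("CVs must be >= 0")
  if (surv_p < 0 || surv_p > 1) stop_invalid("surv_p must be in [0, 1]")
  if (mirror_sd < 0 || nb_dispersion < 0)
    stop_invalid("mirror_sd and nb_dispersion must be >= 0")
  structure(as.list(environment()), class = "effect_spec")
}

trait_truth <- function(design, effects) {
  temps <- design$assay_temps_C
  traits <- names(effects$baseline)
  out <- merge(design$lines, data.frame(assay_temp_C = temps), by = NULL)
  for (tr in traits) {
    ti <- match(out$assay_temp_C, temps)
    eff <- mapply(function(reg, i) effects$regime_effects[[reg]][[tr]][i],
                  out$regime, ti)
    os <- if (tr %in% c("omega", "psi", "mass_M"))
      unname(effects$origin_scale[out$origin]) else 1
    os[is.na(os)] <- 1
    out[[paste0(tr, "_truth")]] <- effects$baseline[[tr]][ti] * eff * os
  }
  out
}

#' Generate a per-line life-history trait table
#'
#' Draws per line x assay temperature trait means around the configured
#' effect structure: truth = baseline(T) x regime multiplier x origin scale,
#' a shared lognormal line-level scale on the reproductive traits (`omega`,
#' `psi`), multiplicative Gaussian noise of relative size `trait_cv`, and an
#' attached SE of `trait_cv` x mean. Deterministic for a fixed design seed.
#'
#' @param design a [design_spec()].
#' @param effects an [effect_spec()].
#' @return a wide data.frame: `line_id`, `origin`, `regime`, `assay_temp_C`,
#'   then `<trait>_mean` / `<trait>_se` for omega, mass_M, d1, psi, d2.
#'   The full parameterization is attached as attribute `generator`.
#' @export
generate_line_traits <- function(design, effects = effect_spec()) {
  stopifnot(inherits(design, "design_spec"), inherits(effects, "effect_spec"))
  truth <- trait_truth(design, effects)
  traits <- names(effects$baseline)
  out <- with_seed(design$seed, {
    line_scale <- stats::setNames(
      exp(stats::rnorm(nrow(design$lines), 0, effects$line_scale_sd)),
      design$lines$line_id)
    res <- truth[c("line_id", "origin", "regime", "assay_temp_C")]
    for (tr in traits) {
      mu <- truth[[paste0(tr, "_truth")]]
      if (tr %in% c("omega", "psi"))
        mu <- mu * line_scale[res$line_id]
      noise <- if (effects$trait_cv > 0)
        stats::rnorm(length(mu), 0, effects$trait_cv) else 0
      m <- mu * (1 + noise)
      m <- pmax(m, 1e-6 * mu)
      res[[paste0(tr, "_mean")]] <- m
      res[[paste0(tr, "_se")]] <- effects$trait_cv * m
    }
    res
  })
  rownames(out) <- NULL
  attr(out, "generator") <- list(design = design, effects = effects)
  out
}

#' Generate dish-level consumption and control assays
#'
#' Per dish: hatched eggs ~ Poisson(`eggs_lambda`), survivors to pupation
#' ~ Binomial(eggs, `surv_p`), mean adult mass ~ Normal around the line's
#' mass truth, and raw host loss = `C_m(T)` x survivors x mass + control
#' drift + Gaussian residual with SD `residual_cv` x mean expected
#' consumption at that temperature. Controls carry drift only. Dishes are
#' allocated cyclically across the design lines so each temperature has
#' exactly `n_dishes_per_temp` dishes.
#'
#' @param design a [design_spec()].
#' @param effects an [effect_spec()].
#' @param n_dishes_per_temp dishes per assay temperature (default 60).
#' @param n_controls_per_temp beetle-free controls per temperature
#'   (default 5).
#' @return a list with data.frames `assays` (dish_id, line_id, regime,
#'   assay_temp_C, eggs, survivors, mean_adult_mass, d2, host_loss_raw) and
#'   `controls` (assay_temp_C, host_loss); generator parameters (including
#'   the implied per-egg consumption per temperature) in attribute
#'   `generator`.
#' @export
generate_consumption <- function(design, effects = effect_spec(),
                                 n_dishes_per_temp = 60,
                                 n_controls_per_temp = 5) {
  stopifnot(inherits(design, "design_spec"), inherits(effects, "effect_spec"))
  temps <- design$assay_temps_C
  C_m <- effects$C_m
  if (is.null(names(C_m))) names(C_m) <- as.character(temps)
  if (!all(as.character(temps) %in% names(C_m)))
    stop_config("effects$C_m must cover every assay temperature")
  truth <- trait_truth(design, effects)

  out <- with_seed(design$seed + 1L, {
    assays <- NULL
    for (Tc in temps) {
      rows <- truth[truth$assay_temp_C == Tc, , drop = FALSE]
      idx <- rep_len(seq_len(nrow(rows)), n_dishes_per_temp)
      lam <- effects$eggs_lambda *
        exp(stats::rnorm(n_dishes_per_temp, 0, effects$eggs_sd_log))
      eggs <- stats::rpois(n_dishes_per_temp, lam)
      survivors <- stats::rbinom(n_dishes_per_temp, eggs, effects$surv_p)
      mass <- stats::rnorm(n_dishes_per_temp,
                           rows$mass_M_truth[idx],
                           effects$trait_cv * rows$mass_M_truth[idx])
      mass <- pmax(mass, 0.1)
      d2 <- stats::rnorm(n_dishes_per_temp, rows$d2_truth[idx],
                         effects$trait_cv * rows$d2_truth[idx])
      cm <- C_m[[as.character(Tc)]]
      expected <- cm * survivors * mass
      noise_sd <- effects$residual_cv * mean(expected)
      raw <- expected + effects$control_drift +
        stats::rnorm(n_dishes_per_temp, 0, noise_sd)
      assays <- rbind(assays, data.frame(
        dish_id = sprintf("T%g_d%03d", Tc, seq_len(n_dishes_per_temp)),
        line_id = rows$line_id[idx], regime = rows$regime[idx],
        assay_temp_C = Tc, eggs = eggs, survivors = survivors,
        mean_adult_mass = mass, d2 = pmax(d2, 1),
        host_loss_raw = pmax(raw, 0)))
    }
    controls <- do.call(rbind, lapply(temps, function(Tc) data.frame(
      assay_temp_C = Tc,
      host_loss = stats::rnorm(n_controls_per_temp, effects$control_drift,
                               effects$control_sd))))
    list(assays = assays, controls = controls)
  })
  implied_CE <- vapply(temps, function(Tc) {
    rows <- truth[truth$assay_temp_C == Tc, , drop = FALSE]
    C_m[[as.character(Tc)]] * effects$surv_p * mean(rows$mass_M_truth)
  }, numeric(1))
  attr(out, "generator") <- list(design = design, effects = effects,
                                 n_dishes_per_temp = n_dishes_per_temp,
                                 C_m_truth = C_m,
                                 C_E_implied = stats::setNames(
                                   implied_CE, as.character(temps)))
  out
}

#' Generate a trade-off gene panel and sample expression set
#'
#' The panel has three quadrants: genes up-regulated by mating and
#' down-regulated by heat (default 21), the reverse polarity (default 113),
#' and concordant genes (default 3, both down). Antagonistic genes mirror
#' their mating log-fold change into the heat response up to lognormal noise
#' `mirror_sd` (0 = exact antisymmetry). Each design line contributes one
#' library per assay temperature (ancestors two); counts are
#' negative-binomial around a gene baseline, with 35 C libraries shifted
#' along the heat-response direction by `shift35` (allocation toward
#' maintenance).
#'
#' @param design a [design_spec()].
#' @param effects an [effect_spec()].
#' @return a list with `panel` (gene_id, lfc_mating, lfc_heat, sig_mating,
#'   sig_heat), `counts` (genes x samples matrix), and `samples`
#'   (sample_id, line_id, regime, origin, assay_temp_C).
#' @export
generate_expression <- function(design, effects = effect_spec()) {
  stopifnot(inherits(design, "design_spec"), inherits(effects, "effect_spec"))
  n_aR <- effects$n_antag_up_R; n_aHS <- effects$n_antag_up_HS
  n_c <- effects$n_concordant
  n_genes <- n_aR + n_aHS + n_c
  with_seed(design$seed + 2L, {
    mag <- function(n) 0.2 + abs(stats::rnorm(n, 1.2, 0.4))
    mirror <- function(x) -x * exp(stats::rnorm(length(x), 0,
                                                effects$mirror_sd))
    lfc_m <- c(mag(n_aR), -mag(n_aHS), -mag(n_c))
    lfc_h <- c(mirror(lfc_m[seq_len(n_aR + n_aHS)]), -mag(n_c))
    panel <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      lfc_mating = lfc_m, lfc_heat = lfc_h,
      sig_mating = TRUE, sig_heat = TRUE)

    reps <- ifelse(design$lines$regime == "ancestor", 2L, 1L)
    samples <- do.call(rbind, lapply(seq_len(nrow(design$lines)), function(i) {
      ln <- design$lines[i, ]
      expand.grid(rep = seq_len(reps[i]), assay_temp_C = design$assay_temps_C,
                  KEEP.OUT.ATTRS = FALSE) |>
        transform(line_id = ln$line_id, regime = ln$regime,
                  origin = ln$origin)
    }))
    samples$sample_id <- sprintf("%s_T%g_r%d", samples$line_id,
                                 samples$assay_temp_C, samples$rep)
    samples <- samples[c("sample_id", "line_id", "regime", "origin",
                         "assay_temp_C")]

    mu0 <- exp(stats::rnorm(n_genes, log(200), 1))
    counts <- vapply(seq_len(nrow(samples)), function(j) {
      shift <- if (samples$assay_temp_C[j] == 35) effects$shift35 else 0
      mu <- mu0 * exp(shift * panel$lfc_heat)
      if (effects$nb_dispersion > 0)
        stats::rnbinom(n_genes, mu = mu, size = 1 / effects$nb_dispersion)
      else stats::rpois(n_genes, mu)
    }, numeric(n_genes))
    dimnames(counts) <- list(panel$gene_id, samples$sample_id)
    list(panel = panel, counts = counts, samples = samples)
  })
}

#' Model-implied life-history trait table
#'
#' Bridges the thermodynamic model to the footprint pipeline: each regime's
#' strategy is optimised at its evolution temperature (cold 23 C, hot 35 C,
#' ancestor 29 C) and frozen; traits at each assay temperature are then
#' derived from the model outputs by fixed mapping constants -- body mass
#' proportional to `M*`, offspring production proportional to `r'` of the
#' frozen strategy at the assay temperature, development time constant. The
#' mapping constants are chosen so the ancestor at 29 C matches the baseline
#' trait means, and are recorded in attribute `mapping`. With this mapping,
#' `omega * mass / d1` is exactly proportional to the model's agricultural
#' impact `M* r'`.
#'
#' @param params a [kinetic_params()].
#' @param design a [design_spec()].
#' @param effects an [effect_spec()] (supplies the anchor trait means).
#' @param cfg an [optimizer_config()].
#' @return a wide trait table as in [generate_line_traits()] (SEs are 0:
#'   the table is model-implied, noise-free), plus `converged` per row.
#' @export
generate_model_truth <- function(params, design, effects = effect_spec(),
                                 cfg = optimizer_config()) {
  stopifnot(inherits(params, "kinetic_params"), inherits(design, "design_spec"))
  evo_temp <- c(cold = 23, hot = 35, ancestor = 29)
  opts <- lapply(evo_temp, function(Tc)
    optimize_strategy(celsius_to_kelvin(Tc), params, cfg))
  anc29 <- growth_rate(celsius_to_kelvin(29), opts$ancestor$strategy, params)
  i29 <- match(29, design$assay_temps_C)
  if (is.na(i29)) i29 <- 1L
  s_mass <- effects$baseline$mass_M[i29] / opts$ancestor$strategy$M
  s_omega <- effects$baseline$omega[i29] / anc29$r_prime
  d1_const <- effects$baseline$d1[i29]

  rows <- merge(design$lines, data.frame(assay_temp_C = design$assay_temps_C),
                by = NULL)
  opt <- opts[rows$regime]
  gr <- mapply(function(o, Tc) {
    growth_rate(celsius_to_kelvin(Tc), o$strategy, params)$r_prime
  }, opt, rows$assay_temp_C)
  out <- data.frame(
    line_id = rows$line_id, origin = rows$origin, regime = rows$regime,
    assay_temp_C = rows$assay_temp_C,
    omega_mean = s_omega * gr, omega_se = 0,
    mass_M_mean = s_mass * vapply(opt, function(o) o$strategy$M, numeric(1)),
    mass_M_se = 0,
    d1_mean = d1_const, d1_se = 0,
    psi_mean = s_omega * gr * (effects$baseline$psi[i29] /
                                 effects$baseline$omega[i29]),
    psi_se = 0,
    d2_mean = d1_const * (effects$baseline$d2[i29] /
                            effects$baseline$d1[i29]),
    d2_se = 0,
    converged = vapply(opt, `[[`, logical(1), "converged"))
  rownames(out) <- NULL
  attr(out, "mapping") <- list(s_mass = s_mass, s_omega = s_omega,
                               d1 = d1_const, evolution_temp_C = evo_temp)
  attr(out, "optima") <- opts
  out
}
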