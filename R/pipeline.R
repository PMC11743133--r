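#' Per-line footprint estimates with bootstrap intervals
#'
#' Computes both footprint metrics for every line x assay temperature from a
#' wide trait table: `phi1` from lifetime offspring, adult mass and
#' development time with the temperature-specific conversion constant, and
#' `phi2` from early fecundity and fastest development with the per-egg
#' constant. Two ancestor-relative contrasts are reported, each with
#' parametric bootstrap 95% intervals:
#' \describe{
#'   \item{`rel_phi1`}{percent change versus the line's own geographic
#'     ancestor reared at 29 C — the common scaling that puts plasticity and
#'     evolution on one axis. It inherits the `C_m(T)/C_m(29)` ratio because
#'     host conversion itself is temperature-specific.}
#'   \item{`evo_rel_phi1`}{percent change versus the respective ancestor at
#'     the \emph{same} assay temperature — the pure evolution effect, the
#'     contrast behind statements like "hot-adapted lines leave an 80%
#'     larger footprint at 35 C".}
#' }
#'
#' @param traits wide trait table (see [generate_line_traits()]).
#' @param C_m named numeric vector of conversion constants keyed by assay
#'   temperature (as character), mg host per mg beetle.
#' @param C_E per-egg consumption constant, mg per egg.
#' @param n_boot bootstrap draws per line (default 2000).
#' @param seed integer seed for all bootstraps.
#' @return a data.frame with per-row `phi1`, `phi1_lo`, `phi1_hi`, `phi2`,
#'   `rel_phi1`, `rel_lo`, `rel_hi`, `evo_rel_phi1`, `evo_lo`, `evo_hi`.
#' @export
footprint_estimates <- function(traits, C_m, C_E, n_boot = 2000, seed = 1L) {
  need <- c("line_id", "origin", "regime", "assay_temp_C",
            "omega_mean", "omega_se", "mass_M_mean", "mass_M_se",
            "d1_mean", "d1_se", "psi_mean", "psi_se", "d2_mean", "d2_se")
  missing <- setdiff(need, names(traits))
  if (length(missing) > 0)
    stop_schema(sprintf("trait table missing column(s): %s",
                        paste(missing, collapse = ", ")))
  if (is.null(names(C_m))) stop_invalid("C_m must be named by temperature")
  cm_of <- function(temp) {
    v <- C_m[as.character(temp)]
    if (any(is.na(v))) stop_config("C_m missing for an assay temperature")
    unname(v)
  }

  n <- nrow(traits)
  out <- traits[c("line_id", "origin", "regime", "assay_temp_C")]
  out$phi1 <- phi1(cm_of(traits$assay_temp_C), traits$omega_mean,
                   traits$mass_M_mean, traits$d1_mean)
  out$phi2 <- phi2(traits$psi_mean, C_E, traits$d2_mean)

  anc29 <- out$regime == "ancestor" & out$assay_temp_C == 29
  if (!any(anc29)) stop_config("no ancestor rows at 29 C: reference undefined")
  ref29 <- match(paste(out$origin, "ancestor", 29),
                 paste(out$origin, out$regime, out$assay_temp_C))
  ref_T <- match(paste(out$origin, "ancestor", out$assay_temp_C),
                 paste(out$origin, out$regime, out$assay_temp_C))
  if (any(is.na(ref_T)))
    stop_config("ancestor rows missing for some assay temperature")
  out$rel_phi1 <- relative_footprint(out$phi1, out$phi1[ref29])
  out$evo_rel_phi1 <- relative_footprint(out$phi1, out$phi1[ref_T])

  # one phi1 draw matrix per row, reused across contrasts so the ancestor's
  # own contrast is exactly degenerate
  draws <- lapply(seq_len(n), function(i) {
    with_seed(seed + i, {
      om <- pmax(stats::rnorm(n_boot, traits$omega_mean[i],
                              traits$omega_se[i]), 0)
      ms <- pmax(stats::rnorm(n_boot, traits$mass_M_mean[i],
                              traits$mass_M_se[i]),
                 1e-6 * traits$mass_M_mean[i])
      dv <- pmax(stats::rnorm(n_boot, traits$d1_mean[i], traits$d1_se[i]),
                 1e-6 * traits$d1_mean[i])
      cm_of(traits$assay_temp_C[i]) * om * ms / dv
    })
  })
  ci <- function(x) unname(stats::quantile(x, c(0.025, 0.975), type = 7))
  q_own <- vapply(draws, ci, numeric(2))
  out$phi1_lo <- q_own[1, ]; out$phi1_hi <- q_own[2, ]
  rel_ci <- vapply(seq_len(n), function(i)
    ci(100 * (draws[[i]] / draws[[ref29[i]]] - 1)), numeric(2))
  out$rel_lo <- rel_ci[1, ]; out$rel_hi <- rel_ci[2, ]
  evo_ci <- vapply(seq_len(n), function(i)
    ci(100 * (draws[[i]] / draws[[ref_T[i]]] - 1)), numeric(2))
  out$evo_lo <- evo_ci[1, ]; out$evo_hi <- evo_ci[2, ]
  out
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes simulate -> consumption -> footprint -> expression trade-off as
#' configured, writing the generated tables, a TSV of per-line footprints and
#' a JSON summary (seeds, config hash, every estimate and interval) under
#' `out_dir`.
#'
#' @param config a config list from [read_run_config()], or a path to a JSON
#'   config file.
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding the configured simulation seed.
#' @return the summary list, invisibly; side effect: files under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim_seed <- as.integer(seed %||% config$simulate$seed)

  design <- design_spec(seed = sim_seed)
  effects <- effect_spec()

  # --- simulate -------------------------------------------------------
  traits <- generate_line_traits(design, effects)
  cons <- generate_consumption(design, effects,
                               config$simulate$n_dishes_per_temp,
                               config$simulate$n_controls_per_temp)
  expr <- generate_expression(design, effects)
  write_table(traits_to_long(traits), file.path(out_dir, "line_traits.tsv"))
  write_table(cons$assays, file.path(out_dir, "consumption_assays.tsv"))
  write_table(cons$controls, file.path(out_dir, "consumption_controls.tsv"))
  write_table(expr$panel, file.path(out_dir, "gene_panel.tsv"))

  # --- consumption ----------------------------------------------------
  assays <- control_correct(cons$assays, cons$controls)
  Cm_est <- vapply(split(assays, assays$assay_temp_C),
                   function(d) estimate_Cm(d)$C_m, numeric(1))
  CE_est <- estimate_CE(assays)
  r2 <- lifehistory_variance_explained(assays)

  # --- footprint ------------------------------------------------------
  fp <- footprint_estimates(traits, Cm_est, CE_est,
                            n_boot = config$bootstrap$n_boot,
                            seed = config$bootstrap$seed)
  write_table(fp, file.path(out_dir, "footprints.tsv"))
  corr <- footprint_correlation(fp$phi1, fp$phi2)
  hot35 <- fp$regime == "hot" & fp$assay_temp_C == 35
  cold23 <- fp$regime == "cold" & fp$assay_temp_C == 23

  # --- expression trade-off -------------------------------------------
  cls <- classify_directions(expr$panel)
  sc <- tradeoff_scores(expr$panel, expr$counts)
  proj <- tradeoff_axis_projection(sc)
  proj_by_T <- tapply(proj$projection, expr$samples$assay_temp_C, mean)

  summary <- list(
    version = config$version,
    config_md5 = config$config_md5,
    seeds = list(simulate = sim_seed, bootstrap = config$bootstrap$seed),
    consumption = list(C_m = as.list(Cm_est), C_E = CE_est,
                       r_squared = as.list(r2),
                       n_floored = attr(assays, "n_floored")),
    footprint = list(
      phi_correlation = corr,
      mean_evo_rel_hot_35 = mean(fp$evo_rel_phi1[hot35]),
      mean_evo_rel_cold_23 = mean(fp$evo_rel_phi1[cold23]),
      per_generation = list(
        hot = per_generation_rate(mean(fp$evo_rel_phi1[hot35]), 60),
        cold = per_generation_rate(mean(fp$evo_rel_phi1[cold23]), 45))),
    expression = list(
      antagonistic = cls$antagonistic, concordant = cls$concordant,
      p_binomial = cls$p_binomial,
      score_correlation = proj$correlation,
      mean_projection_by_temp = as.list(proj_by_T)))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
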