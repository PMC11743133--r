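# Required columns per named table schema.
tf_schemas <- list(
  line_traits = c("line_id", "origin", "regime", "assay_temp_C",
                  "trait", "mean", "se"),
  consumption = c("dish_id", "line_id", "regime", "assay_temp_C", "eggs",
                  "survivors", "mean_adult_mass", "host_loss_raw"),
  controls = c("assay_temp_C", "host_loss"),
  gene_panel = c("gene_id", "lfc_mating", "lfc_heat", "sig_mating",
                 "sig_heat"),
  cm_table = c("assay_temp_C", "C_m"))

tf_numeric_cols <- list(
  line_traits = c("assay_temp_C", "mean", "se"),
  consumption = c("assay_temp_C", "eggs", "survivors", "mean_adult_mass",
                  "host_loss_raw"),
  controls = c("assay_temp_C", "host_loss"),
  gene_panel = c("lfc_mating", "lfc_heat"),
  cm_table = c("assay_temp_C", "C_m"))

#' Read and validate a delimited table against a named schema
#'
#' Delimiter is auto-detected from the extension (`.csv` comma, anything
#' else tab). Supported schemas: `line_traits` (long format: one row per
#' line x temperature x trait), `consumption`, `controls`, `gene_panel`,
#' `cm_table`, and `counts_matrix` (genes x samples, first column gene_id).
#'
#' @param path file path.
#' @param schema schema name (see above).
#' @return a validated data.frame, or a numeric matrix for `counts_matrix`.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) stop_config(sprintf("file not found: %s", path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (schema == "counts_matrix") {
    if (ncol(df) < 2) stop_schema("counts matrix needs gene_id + samples")
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop_schema("counts matrix has non-numeric cells")
    rownames(m) <- as.character(df[[1]])
    return(m)
  }
  cols <- tf_schemas[[schema]]
  if (is.null(cols)) stop_config(sprintf("unknown schema '%s'", schema))
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop_schema(sprintf("schema '%s': missing column(s): %s", schema,
                        paste(missing, collapse = ", ")))
  for (cc in tf_numeric_cols[[schema]]) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]))
    if (length(bad) > 0)
      stop_schema(sprintf("schema '%s': non-numeric value in column '%s', row %d",
                          schema, cc, bad[1]))
    df[[cc]] <- v
  }
  message(sprintf("read %d rows x %d cols from %s [%s]",
                  nrow(df), ncol(df), basename(path), schema))
  df
}

#' Write a table as TSV (or CSV by extension)
#'
#' @param df data.frame.
#' @param path output path; `.csv` writes comma-separated, else tab.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a wide trait table to the long I/O schema (and back)
#'
#' The on-disk `line_traits` schema is long (line_id, origin, regime,
#' assay_temp_C, trait, mean, se); generators and the footprint pipeline use
#' the wide layout with `<trait>_mean` / `<trait>_se` columns.
#'
#' @param wide,long trait tables in the respective layout.
#' @return the converted data.frame.
#' @export
traits_to_long <- function(wide) {
  traits <- unique(sub("_(mean|se)$", "",
                       grep("_(mean|se)$", names(wide), value = TRUE)))
  do.call(rbind, lapply(traits, function(tr) {
    data.frame(wide[c("line_id", "origin", "regime", "assay_temp_C")],
               trait = tr, mean = wide[[paste0(tr, "_mean")]],
               se = wide[[paste0(tr, "_se")]])
  }))
}

#' @rdname traits_to_long
#' @export
traits_to_wide <- function(long) {
  key <- c("line_id", "origin", "regime", "assay_temp_C")
  base <- unique(long[key])
  for (tr in unique(long$trait)) {
    sub <- long[long$trait == tr, ]
    i <- match(interaction(base$line_id, base$assay_temp_C),
               interaction(sub$line_id, sub$assay_temp_C))
    base[[paste0(tr, "_mean")]] <- sub$mean[i]
    base[[paste0(tr, "_se")]] <- sub$se[i]
  }
  rownames(base) <- NULL
  base
}

known_cfg_keys <- list(
  top = c("version", "model", "optimizer", "bootstrap", "simulate", "paths"),
  model = c("a_B", "Ea_B", "kappa_D", "dH_m", "T_m", "dCp", "c", "b"),
  optimizer = c("M_bounds", "grid_n", "refine", "reltol", "n_starts", "seed"),
  bootstrap = c("n_boot", "seed"),
  simulate = c("seed", "n_dishes_per_temp", "n_controls_per_temp"))

#' Read a run configuration (JSON)
#'
#' The config carries a `model` section (every kinetic parameter), optional
#' `optimizer`, `bootstrap`, `simulate` and `paths` sections, and a version
#' stamp. Unknown keys anywhere are rejected; referenced paths must exist.
#'
#' @param path path to a JSON config file.
#' @return a list with `model` (a [kinetic_params()]), `optimizer`
#'   (an [optimizer_config()]), `bootstrap`, `simulate`, `paths`, `version`,
#'   and `config_md5` (hash of the file, embedded in pipeline outputs).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  check_keys <- function(x, allowed, where) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown) > 0)
      stop_config(sprintf("unknown key(s) in %s: %s", where,
                          paste(unknown, collapse = ", ")))
  }
  check_keys(raw, known_cfg_keys$top, "config")
  if (is.null(raw$model)) stop_config("config must have a [model] section")
  check_keys(raw$model, known_cfg_keys$model, "[model]")
  check_keys(raw$optimizer, known_cfg_keys$optimizer, "[optimizer]")
  check_keys(raw$bootstrap, known_cfg_keys$bootstrap, "[bootstrap]")
  check_keys(raw$simulate, known_cfg_keys$simulate, "[simulate]")
  for (p in unlist(raw$paths))
    if (!file.exists(p)) stop_config(sprintf("referenced path missing: %s", p))
  model <- do.call(kinetic_params, as.list(raw$model))
  optimizer <- do.call(optimizer_config, as.list(raw$optimizer %||% list()))
  bootstrap <- utils::modifyList(list(n_boot = 2000, seed = 1L),
                                 as.list(raw$bootstrap %||% list()))
  simulate <- utils::modifyList(list(seed = 1L, n_dishes_per_temp = 60,
                                     n_controls_per_temp = 5),
                                as.list(raw$simulate %||% list()))
  list(model = model, optimizer = optimizer, bootstrap = bootstrap,
       simulate = simulate, paths = raw$paths,
       version = raw$version %||% as.character(utils::packageVersion("thermofoot")),
       config_md5 = unname(tools::md5sum(path)))
}
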