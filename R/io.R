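reach_columns <- c(
  cas = "cas_number", species_name_raw = "species", endpoint_raw = "endpoint",
  qualifier = "qualifier", value = "value", unit = "unit",
  duration_value = "exposure_duration", duration_unit = "duration_unit",
  reliability = "reliability_klimisch"
)

comptox_columns <- c(
  cas = "casrn", species_name_raw = "species_scientific_name",
  endpoint_raw = "toxval_type", qualifier = "toxval_numeric_qualifier",
  value = "toxval_numeric", unit = "toxval_units",
  duration_value = "study_duration_value",
  duration_unit = "study_duration_units", reliability = "qc_status"
)

#' Read a raw ecotoxicity export
#'
#' Reads a delimited table (comma or tab separated, header row, UTF-8) in
#' either the REACH-style or ToxValDB-style column dialect and returns typed
#' raw records ready for [harmonize()]. Mandatory columns missing from the
#' file raise an error naming them; a comma decimal mark can be declared for
#' locale-normalized numerics.
#'
#' @param path File path.
#' @param dialect `"reach"` or `"comptox"`; sets both the column mapping
#'   and the `source` field of the records.
#' @param sep Field separator; default inferred from the file extension
#'   (`.tsv` = tab, otherwise comma).
#' @param decimal_mark `"."` (default) or `","`.
#' @param columns Optional named character vector overriding the dialect's
#'   column mapping (names = record fields, values = file headers).
#' @return Tibble of raw records with a `raw_id` column
#'   (`<dialect>:<line>`).
#' @export
read_ecotox_table <- function(path, dialect = c("reach", "comptox"),
                              sep = NULL, decimal_mark = ".",
                              columns = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  map <- if (dialect == "reach") reach_columns else comptox_columns
  if (!is.null(columns)) map[names(columns)] <- columns

  tbl <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8",
                           check.names = FALSE)
  missing <- setdiff(unname(map), names(tbl))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))

  num <- function(x) {
    if (decimal_mark == ",") x <- gsub(",", ".", gsub("\\.", "", x))
    suppressWarnings(as.numeric(x))
  }
  tibble::tibble(
    raw_id = paste0(dialect, ":", seq_len(nrow(tbl))),
    cas = tbl[[map[["cas"]]]],
    source = if (dialect == "reach") "REACH" else "COMPTOX",
    species_name_raw = tbl[[map[["species_name_raw"]]]],
    endpoint_raw = tbl[[map[["endpoint_raw"]]]],
    qualifier = tbl[[map[["qualifier"]]]],
    value = num(tbl[[map[["value"]]]]),
    unit = tbl[[map[["unit"]]]],
    duration_value = num(tbl[[map[["duration_value"]]]]),
    duration_unit = tbl[[map[["duration_unit"]]]],
    reliability = tbl[[map[["reliability"]]]]
  )
}

#' Read a chemical-property table
#'
#' Expects columns `cas`, `smiles`, `mw`, `log_kow`, `koc`, `kaw`,
#' `kdeg_water`, `pka_class` (missing optional columns become `NA`).
#'
#' @param path CSV file path.
#' @return Tibble of chemical records with normalized CAS.
#' @export
read_chemicals_table <- function(path) {
  tbl <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  if (!"cas" %in% names(tbl)) stop("missing mandatory column(s): cas")
  for (col in c("smiles", "pka_class"))
    if (is.null(tbl[[col]])) tbl[[col]] <- NA_character_
  for (col in c("mw", "log_kow", "koc", "kaw", "kdeg_water"))
    if (is.null(tbl[[col]])) tbl[[col]] <- NA_real_
  tbl$cas <- normalize_cas(tbl$cas)
  tbl
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Unknown keys are rejected.
#'
#' @param harmonization A [harmonization_config()].
#' @param extrapolation_factors Factor table
#'   ([default_extrapolation_factors()]).
#' @param landscape Landscape list ([default_landscape()]).
#' @param variant Fate variant selection: `"both"` (default),
#'   `"standard"`, or `"pfas_adapted"`.
#' @param hc20_method Passed to [compute_effect_factors()].
#' @param seed Integer seed governing any randomness.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(harmonization = harmonization_config(),
                            extrapolation_factors = default_extrapolation_factors(),
                            landscape = default_landscape(),
                            variant = "both",
                            hc20_method = "ssd",
                            seed = 1L) {
  structure(
    list(harmonization = harmonization,
         extrapolation_factors = extrapolation_factors,
         landscape = landscape,
         variant = match.arg(variant, c("both", "standard", "pfas_adapted")),
         hc20_method = match.arg(hc20_method, c("ssd", "geomean")),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full characterization pipeline
#'
#' Harmonize raw records, compute effect factors, fate and exposure for the
#' selected variants, assemble the four-methodology CFs, run the
#' methodology-pair regressions, and (when SMILES are available) the
#' perfluorinated-carbon group analysis. Optionally writes every table as
#' CSV plus JSON sidecars (audit, regressions, manifest) to `out_dir`.
#'
#' @param raw Raw ecotoxicity records (see [harmonize()]).
#' @param chemicals Chemical-property tibble.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List of class `pfascf_run`: `harmonized`, `audit`, `efs`,
#'   `fate`, `cfs`, `regressions`, `pfc_groups`, `manifest`.
#' @export
run_pipeline <- function(raw, chemicals, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  set_rng(config$seed)
  harm <- harmonize(raw, config$harmonization)
  efs <- compute_effect_factors(harm, config$extrapolation_factors,
                                config$hc20_method)
  fate <- compute_fate_exposure(chemicals, config$variant, config$landscape)
  cfs <- assemble_cfs(efs, fate)

  regressions <- list()
  safe_reg <- function(x, y) tryCatch(log_regression(x, y),
                                      error = function(e) NULL)
  regressions$cf_hc20_usetox_vs_adapted <-
    safe_reg(cfs$cf_usetox_hc20, cfs$cf_adapted_hc20)
  regressions$cf_hc50_usetox_vs_adapted <-
    safe_reg(cfs$cf_usetox_hc50, cfs$cf_adapted_hc50)
  regressions$cf_hc20_vs_hc50_usetox <-
    safe_reg(cfs$cf_usetox_hc20, cfs$cf_usetox_hc50)
  regressions$cf_hc20_vs_hc50_adapted <-
    safe_reg(cfs$cf_adapted_hc20, cfs$cf_adapted_hc50)
  regressions$ef_hc20_vs_hc50 <- safe_reg(efs$ef_hc20, efs$ef_hc50)

  pfc_groups <- NULL
  if (!is.null(chemicals$smiles) && any(!is.na(chemicals$smiles))) {
    chem <- tibble::as_tibble(chemicals)
    chem$n_pfc <- count_perfluorinated_carbons(chem$smiles)
    joined <- dplyr::inner_join(
      cfs, chem[, c("cas", "n_pfc")], by = "cas")
    pfc_groups <- list(
      cf_hc20 = group_by_pfc(log10(joined$cf_usetox_hc20), joined$n_pfc),
      cf_hc50 = group_by_pfc(log10(joined$cf_usetox_hc50), joined$n_pfc),
      ef_hc20 = group_by_pfc(
        log10(joined$ef_hc20), joined$n_pfc),
      ef_hc50 = group_by_pfc(
        log10(joined$ef_hc50), joined$n_pfc)
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pfascf")),
    seed = config$seed,
    variant = config$variant,
    hc20_method = config$hc20_method,
    config_hash = rlang::hash(config),
    n_raw = nrow(tibble::as_tibble(raw)),
    n_harmonized = harm$audit$n_out,
    n_chemicals_ef = nrow(efs),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  bundle <- structure(
    list(harmonized = harm$records, audit = harm$audit, efs = efs,
         fate = fate, cfs = cfs, regressions = regressions,
         pfc_groups = pfc_groups, manifest = manifest),
    class = "pfascf_run"
  )
  if (!is.null(out_dir)) write_run_bundle(bundle, out_dir)
  bundle
}

#' Write a pipeline run bundle to disk
#'
#' CSV for tables (a `#` comment line documents units), JSON for the audit,
#' regression summaries and run manifest.
#'
#' @param bundle A `pfascf_run` object.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_csv_units <- function(df, file, units) {
    con <- file(file.path(out_dir, file), "w")
    on.exit(close(con))
    writeLines(paste("#", units), con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  write_csv_units(bundle$harmonized, "harmonized.csv",
                  "value_mg_per_L in mg/L")
  write_csv_units(bundle$efs, "effect_factors.csv",
                  "HC in kg/m3; EF in PAF.m3/kg")
  write_csv_units(bundle$fate, "fate_exposure.csv",
                  "ff_days in days; xf dimensionless; rates in 1/day")
  write_csv_units(bundle$cfs, "characterization_factors.csv",
                  "CF in PAF.m3.day/kg emitted to freshwater")
  jsonlite::write_json(
    list(n_in = bundle$audit$n_in, n_out = bundle$audit$n_out,
         drops = as.list(bundle$audit$drops)),
    file.path(out_dir, "harmonization_audit.json"), auto_unbox = TRUE)
  regs <- lapply(bundle$regressions, function(r)
    if (is.null(r)) NULL else unclass(r))
  jsonlite::write_json(regs, file.path(out_dir, "regressions.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' @export
print.pfascf_run <- function(x, ...) {
  cat("pfascf pipeline run:\n")
  cat("  raw records:      ", x$manifest$n_raw, "\n")
  cat("  harmonized:       ", x$manifest$n_harmonized, "\n")
  cat("  chemicals with EF:", x$manifest$n_chemicals_ef, "\n")
  cat("  fate variant(s):  ", x$manifest$variant, "\n")
  invisible(x)
}
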