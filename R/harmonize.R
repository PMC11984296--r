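#' Harmonization configuration
#'
#' Bundles every tunable of the four-step harmonization: chronic-duration
#' thresholds, the CompTox QC pass token, qualifier strictness, endpoint
#' synonym handling, and an optional molecular-weight lookup for molar unit
#' conversion.
#'
#' @param chronic_thresholds Named numeric vector of minimum chronic
#'   durations (days) per species group; see [default_chronic_thresholds()].
#' @param comptox_pass_token QC-status string (case-insensitive) that marks a
#'   CompTox record reliable. Default `"pass"`.
#' @param strict_qualifier If `FALSE` (default) an absent numeric qualifier
#'   is read as `"="`; if `TRUE` such records are dropped.
#' @param loec_as How to treat LOEC labels: `NA` (default, reject) or one of
#'   `"EC10"`, `"EC50"`, `"NOEC"`.
#' @param regime_from_label If `TRUE`, records with no usable duration fall
#'   back to "chronic"/"acute" text in the endpoint label or effect
#'   description; default `FALSE` (such records are dropped).
#' @param mw_lookup Optional named numeric vector (names = normalized CAS)
#'   of molecular weights (g/mol) enabling mol/L-family unit conversion.
#' @param species_mapping Mapping table, defaults to the bundled
#'   [species_map()].
#' @return A list of class `harmonization_config`.
#' @export
harmonization_config <- function(chronic_thresholds = default_chronic_thresholds(),
                                 comptox_pass_token = "pass",
                                 strict_qualifier = FALSE,
                                 loec_as = NA,
                                 regime_from_label = FALSE,
                                 mw_lookup = NULL,
                                 species_mapping = NULL) {
  stopifnot(all(species_groups() %in% names(chronic_thresholds)))
  if (!is.na(loec_as)) loec_as <- match.arg(loec_as, c("EC10", "EC50", "NOEC"))
  structure(
    list(
      chronic_thresholds = chronic_thresholds,
      comptox_pass_token = tolower(comptox_pass_token),
      strict_qualifier = isTRUE(strict_qualifier),
      loec_as = loec_as,
      regime_from_label = isTRUE(regime_from_label),
      mw_lookup = mw_lookup,
      species_mapping = species_mapping
    ),
    class = "harmonization_config"
  )
}

drop_reasons <- function() {
  c("no_cas", "unreliable", "bad_qualifier", "unmapped_species",
    "missing_duration_policy", "bad_unit", "missing_value", "bad_endpoint",
    "duplicate")
}

#' Reliability screen for a raw ecotoxicity record
#'
#' REACH records are reliable iff their Klimisch score is 1 or 2; CompTox
#' records iff their QC status equals the configured pass token
#' (case-insensitive). A missing reliability field is unreliable.
#'
#' @param source Character vector, `"REACH"` or `"COMPTOX"`.
#' @param reliability Character/numeric vector: Klimisch score or QC status.
#' @param config A [harmonization_config()].
#' @return Logical vector: keep (`TRUE`) or drop.
#' @export
filter_reliability <- function(source, reliability,
                               config = harmonization_config()) {
  src <- toupper(trimws(as.character(source)))
  rel <- trimws(as.character(reliability))
  rel[!nzchar(rel)] <- NA_character_
  keep <- rep(FALSE, length(src))
  is_reach <- src == "REACH"
  klim <- suppressWarnings(as.numeric(rel))
  keep[is_reach] <- !is.na(klim[is_reach]) & klim[is_reach] %in% c(1, 2)
  is_ct <- src == "COMPTOX"
  keep[is_ct] <- !is.na(rel[is_ct]) &
    tolower(rel[is_ct]) == config$comptox_pass_token
  keep
}

#' Qualifier screen: only exact ("=") values are retained
#'
#' @param qualifier Character vector of numeric qualifiers.
#' @inheritParams filter_reliability
#' @return Logical keep vector. Whitespace is stripped; an absent qualifier
#'   counts as `"="` unless `strict_qualifier` is set.
#' @export
filter_qualifier <- function(qualifier, config = harmonization_config()) {
  q <- trimws(as.character(qualifier))
  absent <- is.na(q) | !nzchar(q)
  ifelse(absent, !config$strict_qualifier, q == "=")
}

#' Standardize exposure duration to days
#'
#' @param value Positive numeric durations.
#' @param unit Character units: minutes (`min`), hours (`h`, `hr`, `hour`),
#'   days (`d`, `day`), weeks (`wk`, `week`). Case-insensitive, plural forms
#'   accepted.
#' @return Numeric vector of days; `NA` for unknown units or non-positive
#'   values (rejection).
#' @examples
#' standardize_duration(c(96, 2, 30), c("h", "wk", "min"))
#' @export
standardize_duration <- function(value, unit) {
  u <- tolower(trimws(as.character(unit)))
  u <- sub("s$", "", u)
  per_day <- c(
    min = 1440, minute = 1440,
    h = 24, hr = 24, hour = 24,
    d = 1, day = 1,
    wk = 1 / 7, week = 1 / 7
  )
  factor <- per_day[u]
  v <- as.numeric(value)
  out <- v / unname(factor)
  out[is.na(factor) | is.na(v) | v <= 0] <- NA_real_
  out
}

#' Classify a test as acute or chronic
#'
#' Chronic iff the exposure duration meets or exceeds the group-specific
#' threshold; shorter exposures are acute.
#'
#' @param species_group Character vector of species groups.
#' @param duration_days Numeric durations in days.
#' @param thresholds Named threshold vector (days), defaults to
#'   [default_chronic_thresholds()].
#' @return Character vector `"acute"`/`"chronic"`; `NA` where duration or
#'   group is missing.
#' @export
classify_regime <- function(species_group, duration_days,
                            thresholds = default_chronic_thresholds()) {
  thr <- unname(thresholds[as.character(species_group)])
  out <- ifelse(duration_days >= thr, "chronic", "acute")
  out[is.na(duration_days) | is.na(thr)] <- NA_character_
  out
}

#' Standardize effect concentrations to mg/L
#'
#' Handles the mass-per-volume family (ng/L through g/L, g/m3, mg/m3, ppm,
#' ppb) directly; molar units (mol/L family) convert only when a molecular
#' weight is supplied.
#'
#' @param value Numeric effect values.
#' @param unit Character unit strings.
#' @param mw Optional molecular weight (g/mol), recycled; needed for molar
#'   units only.
#' @return Numeric mg/L; `NA` where the unit is unconvertible (rejection).
#' @examples
#' standardize_value(c(500, 2, 1), c("ug/L", "g/m3", "mol/L"), mw = 100)
#' @export
standardize_value <- function(value, unit, mw = NA_real_) {
  u <- tolower(gsub("\\s+", "", as.character(unit)))
  u <- gsub("µ|μ", "u", u)   # micro sign variants -> "u"
  to_mg_l <- c(
    "mg/l" = 1, "ug/l" = 1e-3, "ng/l" = 1e-6, "g/l" = 1e3,
    "g/m3" = 1, "mg/m3" = 1e-3, "ug/m3" = 1e-6,
    "ppm" = 1, "ppb" = 1e-3
  )
  molar <- c("mol/l" = 1e3, "mmol/l" = 1, "umol/l" = 1e-3)
  v <- as.numeric(value)
  mw <- rep_len(as.numeric(mw), length(v))
  out <- v * unname(to_mg_l[u])
  is_molar <- u %in% names(molar)
  out[is_molar] <- v[is_molar] * unname(molar[u[is_molar]]) * mw[is_molar]
  out[is.na(v) | v <= 0] <- NA_real_
  out
}

#' Consolidate endpoint labels into EC10 / EC50 / NOEC
#'
#' Lethal- and inhibition-concentration synonyms fold into the effect
#' concentration of the same severity (LC50/IC50 -> EC50; LC10/IC10 -> EC10);
#' NOEL folds into NOEC. LOEC is rejected by default (configurable).
#'
#' @param endpoint_raw Character vector of raw endpoint labels.
#' @inheritParams filter_reliability
#' @return Character vector in `{"EC10","EC50","NOEC"}`; `NA` = rejection.
#' @export
consolidate_endpoint <- function(endpoint_raw,
                                 config = harmonization_config()) {
  e <- toupper(gsub("[^A-Za-z0-9]", "", as.character(endpoint_raw)))
  out <- rep(NA_character_, length(e))
  out[e %in% c("EC10", "LC10", "IC10")] <- "EC10"
  out[e %in% c("EC50", "LC50", "IC50")] <- "EC50"
  out[e %in% c("NOEC", "NOEL")] <- "NOEC"
  if (!is.na(config$loec_as)) out[e %in% c("LOEC", "LOEL")] <- config$loec_as
  out
}

#' Remove duplicate harmonized records
#'
#' Two records are duplicates when they agree on chemical, species, endpoint,
#' regime and on the effect value rounded to 6 significant digits (absorbing
#' re-export float noise without merging genuinely distinct tests). The first
#' record in input order is retained.
#'
#' @param records Harmonized tibble with columns `cas`, `species_common`,
#'   `endpoint`, `regime`, `value_mg_per_L`.
#' @return List with `records` (deduplicated tibble) and `n_dropped`.
#' @export
deduplicate_records <- function(records) {
  key <- paste(records$cas, records$species_common, records$endpoint,
               records$regime, signif(records$value_mg_per_L, 6), sep = "\r")
  dup <- duplicated(key)
  list(records = records[!dup, , drop = FALSE], n_dropped = sum(dup))
}

#' Harmonize raw ecotoxicity records
#'
#' Applies the four-step harmonization in a fixed order — CAS normalization,
#' reliability screen, qualifier screen, species mapping, duration
#' standardization and acute/chronic classification, unit standardization,
#' endpoint consolidation, deduplication — recording one drop reason per
#' excluded record. The audit satisfies `n_in = n_out + sum(drops)` by
#' construction.
#'
#' @param raw Tibble/data.frame of raw records with columns `cas`, `source`
#'   (`"REACH"`/`"COMPTOX"`), `species_name_raw`, `endpoint_raw`, `qualifier`,
#'   `value`, `unit`, `duration_value`, `duration_unit`, `reliability`;
#'   optionally `raw_id` and `effect_description`.
#' @param config A [harmonization_config()].
#' @return List of class `pfas_harmonization` with elements `records` (the
#'   harmonized tibble: `cas`, `species_common`, `species_group`, `endpoint`,
#'   `regime`, `value_mg_per_L`, `source`, `raw_id`) and `audit` (list:
#'   `n_in`, `n_out`, named `drops`, and `drop_reason` per input record).
#' @export
harmonize <- function(raw, config = harmonization_config()) {
  raw <- tibble::as_tibble(raw)
  n_in <- nrow(raw)
  mapping <- config$species_mapping
  if (is.null(mapping)) mapping <- species_map()

  empty <- tibble::tibble(
    cas = character(), species_common = character(),
    species_group = character(), endpoint = character(),
    regime = character(), value_mg_per_L = numeric(),
    source = character(), raw_id = character()
  )
  if (n_in == 0L) {
    audit <- list(n_in = 0L, n_out = 0L,
                  drops = stats::setNames(integer(length(drop_reasons())),
                                          drop_reasons()),
                  drop_reason = character())
    return(structure(list(records = empty, audit = audit),
                     class = "pfas_harmonization"))
  }

  if (is.null(raw$raw_id)) raw$raw_id <- sprintf("rec%06d", seq_len(n_in))
  reason <- rep(NA_character_, n_in)
  flag <- function(fail, why) {
    reason[is.na(reason) & fail] <<- why
  }

  cas_norm <- normalize_cas(raw$cas)
  flag(is.na(cas_norm), "no_cas")
  flag(!filter_reliability(raw$source, raw$reliability, config), "unreliable")
  flag(!filter_qualifier(raw$qualifier, config), "bad_qualifier")

  sp <- map_species(raw$species_name_raw, mapping)
  flag(is.na(sp$species_common), "unmapped_species")

  dur_days <- standardize_duration(raw$duration_value, raw$duration_unit)
  regime <- classify_regime(sp$species_group, dur_days,
                            config$chronic_thresholds)
  if (config$regime_from_label) {
    label <- tolower(paste(raw$endpoint_raw,
                           if (is.null(raw$effect_description)) "" else
                             raw$effect_description))
    regime[is.na(regime) & grepl("chronic", label)] <- "chronic"
    regime[is.na(regime) & grepl("acute", label)] <- "acute"
  }
  flag(is.na(regime), "missing_duration_policy")

  mw <- if (is.null(config$mw_lookup)) NA_real_ else
    unname(config$mw_lookup[cas_norm])
  value_mg <- standardize_value(raw$value, raw$unit, mw)
  v_raw <- suppressWarnings(as.numeric(raw$value))
  missing_val <- is.na(v_raw) | v_raw <= 0
  flag(missing_val, "missing_value")
  flag(is.na(value_mg), "bad_unit")

  endpoint <- consolidate_endpoint(raw$endpoint_raw, config)
  flag(is.na(endpoint), "bad_endpoint")

  keep <- is.na(reason)
  records <- tibble::tibble(
    cas = cas_norm[keep],
    species_common = sp$species_common[keep],
    species_group = sp$species_group[keep],
    endpoint = endpoint[keep],
    regime = regime[keep],
    value_mg_per_L = value_mg[keep],
    source = toupper(trimws(as.character(raw$source[keep]))),
    raw_id = raw$raw_id[keep]
  )

  dd <- deduplicate_records(records)
  dup_ids <- setdiff(records$raw_id, dd$records$raw_id)
  reason[raw$raw_id %in% dup_ids] <- "duplicate"
  records <- dd$records

  drops <- stats::setNames(integer(length(drop_reasons())), drop_reasons())
  tab <- table(reason[!is.na(reason)])
  drops[names(tab)] <- as.integer(tab)
  audit <- list(n_in = n_in, n_out = nrow(records), drops = drops,
                drop_reason = reason)
  stopifnot(audit$n_in == audit$n_out + sum(audit$drops))
  structure(list(records = records, audit = audit),
            class = "pfas_harmonization")
}

#' @export
print.pfas_harmonization <- function(x, ...) {
  cat("Harmonized ecotoxicity dataset:", x$audit$n_out, "of", x$audit$n_in,
      "records retained\n")
  d <- x$audit$drops[x$audit$drops > 0]
  if (length(d)) {
    cat("Drops:\n")
    for (nm in names(d)) cat("  ", nm, ": ", d[[nm]], "\n", sep = "")
  }
  invisible(x)
}
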