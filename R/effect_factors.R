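#' Default endpoint/regime extrapolation factors
#'
#' Multipliers taking a harmonized effect value to its chronic EC10
#' equivalent (`to_ec10eq`) and chronic EC50 equivalent (`to_ec50eq`):
#' `value_target = value * multiplier`. Defaults encode the conventional
#' acute-to-chronic ratio of 2 (chronic = acute / 2), an EC50-to-EC10 ratio
#' of 2, and NOEC treated as equivalent to chronic EC10 (hence NOEC to
#' EC50eq multiplies by 2). Identity multipliers hold for chronic EC10 ->
#' EC10eq and chronic EC50 -> EC50eq. The table is data, not code: pass any
#' tibble with the same columns to override.
#'
#' @return Tibble with columns `endpoint`, `regime`, `to_ec10eq`,
#'   `to_ec50eq`.
#' @export
default_extrapolation_factors <- function() {
  tibble::tribble(
    ~endpoint, ~regime,   ~to_ec10eq, ~to_ec50eq,
    "EC10",    "chronic", 1,          2,
    "EC10",    "acute",   0.5,        1,
    "EC50",    "chronic", 0.5,        1,
    "EC50",    "acute",   0.25,       0.5,
    "NOEC",    "chronic", 1,          2,
    "NOEC",    "acute",   0.5,        1
  )
}

#' Extrapolate an effect value to a chronic-equivalent endpoint
#'
#' @param value Numeric effect values (mg/L).
#' @param endpoint,regime Character vectors locating each value in the
#'   factor table.
#' @param table Extrapolation-factor tibble
#'   ([default_extrapolation_factors()]).
#' @param target `"ec10eq"` or `"ec50eq"` (chronic equivalents).
#' @return Numeric mg/L; `NA` where the (endpoint, regime) pair is absent
#'   from the table (the record is excluded from that pool).
#' @export
extrapolate <- function(value, endpoint, regime,
                        table = default_extrapolation_factors(),
                        target = c("ec10eq", "ec50eq")) {
  target <- match.arg(target)
  col <- if (target == "ec10eq") table$to_ec10eq else table$to_ec50eq
  idx <- match(paste(endpoint, regime), paste(table$endpoint, table$regime))
  value * col[idx]
}

geomean <- function(x) exp(mean(log(x)))

#' Per-species geometric aggregation of chronic-equivalent values
#'
#' For one or many chemicals, computes the geometric mean of the available
#' chronic EC10-equivalent and EC50-equivalent values per (chemical,
#' species). Species with no usable value in a pool are omitted from that
#' pool only.
#'
#' @param records Tibble with columns `cas`, `species_common`,
#'   `species_group`, `value_ec10eq`, `value_ec50eq` (either value column
#'   may contain `NA`).
#' @return Tibble: `cas`, `species_common`, `species_group`,
#'   `geomean_ec10eq_chronic`, `geomean_ec50eq_chronic`, `n_points`.
#' @export
aggregate_species <- function(records) {
  records |>
    dplyr::group_by(.data$cas, .data$species_common, .data$species_group) |>
    dplyr::summarise(
      geomean_ec10eq_chronic = if (any(!is.na(.data$value_ec10eq)))
        geomean(.data$value_ec10eq[!is.na(.data$value_ec10eq)]) else NA_real_,
      geomean_ec50eq_chronic = if (any(!is.na(.data$value_ec50eq)))
        geomean(.data$value_ec50eq[!is.na(.data$value_ec50eq)]) else NA_real_,
      n_points = dplyr::n(),
      .groups = "drop"
    )
}

#' Fit the lognormal species sensitivity distribution
#'
#' The SSD is normal in log10 concentration: `mu` is the arithmetic mean and
#' `sigma` the sample standard deviation (n-1 denominator) of the log10
#' species sensitivities; `sigma = 0` for a single species.
#'
#' @param species_values Positive numeric vector of per-species sensitivities
#'   (mg/L).
#' @return List `mu`, `sigma` (log10 mg/L units), `n`; `NULL` for an empty
#'   input.
#' @export
fit_ssd <- function(species_values) {
  x <- species_values[!is.na(species_values)]
  if (length(x) == 0L) return(NULL)
  stopifnot(all(x > 0))
  lg <- log10(x)
  list(mu = mean(lg),
       sigma = if (length(lg) > 1L) stats::sd(lg) else 0,
       n = length(lg))
}

#' Hazardous concentration for 20% of species (HC20)
#'
#' The 20th percentile of the lognormal SSD, `10^(mu - z * sigma)` mg/L
#' converted to kg/m3, with `z = qnorm(0.8)` (0.8416212). Setting
#' `method = "geomean"` returns `10^mu` instead (sensitivity variant).
#'
#' @param mu,sigma SSD parameters in log10(mg/L).
#' @param z Standard-normal deviate for the 20th percentile.
#' @param method `"ssd"` (default) or `"geomean"`.
#' @return HC20 in kg/m3.
#' @export
hc20 <- function(mu, sigma, z = stats::qnorm(0.8),
                 method = c("ssd", "geomean")) {
  method <- match.arg(method)
  mg_l <- if (method == "ssd") 10^(mu - z * sigma) else 10^mu
  mg_l * 1e-3
}

#' Hazardous concentration for 50% of species (HC50)
#'
#' Geometric mean of per-species chronic EC50-equivalent values, i.e. the
#' median of the lognormal SSD, in kg/m3.
#'
#' @param species_geomeans Positive per-species values (mg/L).
#' @return HC50 in kg/m3; `NA` for an empty input.
#' @export
hc50 <- function(species_geomeans) {
  x <- species_geomeans[!is.na(species_geomeans)]
  if (length(x) == 0L) return(NA_real_)
  stopifnot(all(x > 0))
  geomean(x) * 1e-3
}

#' Effect factor from HC20 (chronic EC10 equivalents)
#'
#' `EF = 0.2 / HC20`, in PAF m3/kg.
#' @param hc20 HC20 in kg/m3, positive.
#' @return EF in PAF m3/kg.
#' @export
effect_factor_hc20 <- function(hc20) {
  stopifnot(all(is.na(hc20) | hc20 > 0))
  0.2 / hc20
}

#' Effect factor from HC50 (chronic EC50 equivalents)
#'
#' `EF = 0.5 / HC50`, in PAF m3/kg.
#' @param hc50 HC50 in kg/m3, positive.
#' @return EF in PAF m3/kg.
#' @export
effect_factor_hc50 <- function(hc50) {
  stopifnot(all(is.na(hc50) | hc50 > 0))
  0.5 / hc50
}

#' Species-group and trophic-level coverage
#'
#' Trophic levels: producers (algae, aquatic plants), primary consumers
#' (crustaceans, molluscs, insects/spiders, invertebrates), secondary
#' consumers (fish, amphibians). The "other" group counts toward group
#' coverage but no trophic level.
#'
#' @param groups Character vector of species groups present for a chemical.
#' @return List `n_species_groups`, `n_trophic_levels` (0-3).
#' @export
trophic_coverage <- function(groups) {
  g <- unique(groups[!is.na(groups)])
  levels <- list(
    producers = c("algae", "aquatic_plants"),
    primary = c("crustaceans", "molluscs", "insects_spiders", "invertebrates"),
    secondary = c("fish", "amphibians")
  )
  n_lvl <- sum(vapply(levels, function(m) any(g %in% m), logical(1)))
  list(n_species_groups = length(g), n_trophic_levels = n_lvl)
}

#' Compute per-chemical effect factors from a harmonized dataset
#'
#' Chains extrapolation to chronic equivalents, per-species geometric
#' aggregation, the lognormal SSD fit with HC20 at the 20th percentile, the
#' HC50 geometric mean, and the two effect factors, carrying data-coverage
#' diagnostics. Chemicals with no usable value in a pool have `NA` for that
#' pool's HC and EF.
#'
#' @param harmonized Harmonized records tibble (see [harmonize()]) or a
#'   `pfas_harmonization` object.
#' @param factors Extrapolation-factor table.
#' @param hc20_method Passed to [hc20()].
#' @return Tibble, one row per chemical: `cas`, `hc20_ec10eq_kg_m3`,
#'   `hc50_ec50eq_kg_m3`, `ef_hc20`, `ef_hc50`, `ssd_mu`, `ssd_sigma`,
#'   `n_species`, `n_species_groups`, `n_trophic_levels`, `n_datapoints`.
#' @export
compute_effect_factors <- function(harmonized,
                                   factors = default_extrapolation_factors(),
                                   hc20_method = c("ssd", "geomean")) {
  hc20_method <- match.arg(hc20_method)
  if (inherits(harmonized, "pfas_harmonization"))
    harmonized <- harmonized$records
  rec <- tibble::as_tibble(harmonized)
  if (nrow(rec) == 0L) {
    return(tibble::tibble(
      cas = character(), hc20_ec10eq_kg_m3 = numeric(),
      hc50_ec50eq_kg_m3 = numeric(), ef_hc20 = numeric(),
      ef_hc50 = numeric(), ssd_mu = numeric(), ssd_sigma = numeric(),
      n_species = integer(), n_species_groups = integer(),
      n_trophic_levels = integer(), n_datapoints = integer()
    ))
  }
  rec$value_ec10eq <- extrapolate(rec$value_mg_per_L, rec$endpoint,
                                  rec$regime, factors, "ec10eq")
  rec$value_ec50eq <- extrapolate(rec$value_mg_per_L, rec$endpoint,
                                  rec$regime, factors, "ec50eq")
  agg <- aggregate_species(rec)

  agg |>
    dplyr::group_by(.data$cas) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_ssd(d$geomean_ec10eq_chronic)
      h20 <- if (is.null(fit)) NA_real_ else
        hc20(fit$mu, fit$sigma, method = hc20_method)
      h50 <- hc50(d$geomean_ec50eq_chronic)
      cov <- trophic_coverage(d$species_group)
      tibble::tibble(
        hc20_ec10eq_kg_m3 = h20,
        hc50_ec50eq_kg_m3 = h50,
        ef_hc20 = if (is.na(h20)) NA_real_ else effect_factor_hc20(h20),
        ef_hc50 = if (is.na(h50)) NA_real_ else effect_factor_hc50(h50),
        ssd_mu = if (is.null(fit)) NA_real_ else fit$mu,
        ssd_sigma = if (is.null(fit)) NA_real_ else fit$sigma,
        n_species = nrow(d),
        n_species_groups = cov$n_species_groups,
        n_trophic_levels = cov$n_trophic_levels,
        n_datapoints = sum(d$n_points)
      )
    }) |>
    dplyr::ungroup()
}
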