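#' Characterization factor as the fate-exposure-effect product
#'
#' `CF = FF * XF * EF`, in PAF m3 day per kg emitted to freshwater. Any
#' absent component yields an absent CF.
#'
#' @param ff_days Fate factor (days).
#' @param xf Dissolved fraction in (0, 1].
#' @param ef Effect factor (PAF m3/kg).
#' @return CF in PAF m3 day/kg.
#' @export
characterization_factor <- function(ff_days, xf, ef) {
  ff_days * xf * ef
}

#' Assemble characterization factors for the four methodologies
#'
#' Combines a per-chemical effect-factor table with the per-variant
#' fate/exposure table into the four CF columns: standard (Kow-based)
#' fate/exposure with the HC50- and HC20-based effect factors, and
#' PFAS-adapted (Koc-based) fate/exposure with the same two effect factors.
#' Effect factors are computed once and shared across variants, so the
#' HC20/HC50 CF ratio is identical between variants by construction.
#'
#' @param efs Effect-factor tibble from [compute_effect_factors()].
#' @param fate Fate/exposure tibble from [compute_fate_exposure()] with
#'   both variants.
#' @return Tibble: `cas`, `cf_usetox_hc20`, `cf_usetox_hc50`,
#'   `cf_adapted_hc20`, `cf_adapted_hc50`, plus the component columns
#'   `ef_hc20`, `ef_hc50`, `ff_standard`, `xf_standard`, `ff_adapted`,
#'   `xf_adapted` (NA where a component is unavailable).
#' @export
assemble_cfs <- function(efs, fate) {
  wide <- fate |>
    dplyr::select("cas", "variant", "ff_days", "xf") |>
    tidyr::pivot_wider(names_from = "variant",
                       values_from = c("ff_days", "xf"))
  for (col in c("ff_days_standard", "xf_standard",
                "ff_days_pfas_adapted", "xf_pfas_adapted"))
    if (is.null(wide[[col]])) wide[[col]] <- NA_real_

  efs |>
    dplyr::select("cas", "ef_hc20", "ef_hc50") |>
    dplyr::left_join(wide, by = "cas") |>
    dplyr::mutate(
      ff_standard = .data$ff_days_standard,
      xf_standard = .data$xf_standard,
      ff_adapted = .data$ff_days_pfas_adapted,
      xf_adapted = .data$xf_pfas_adapted,
      cf_usetox_hc20 = characterization_factor(.data$ff_standard,
                                               .data$xf_standard,
                                               .data$ef_hc20),
      cf_usetox_hc50 = characterization_factor(.data$ff_standard,
                                               .data$xf_standard,
                                               .data$ef_hc50),
      cf_adapted_hc20 = characterization_factor(.data$ff_adapted,
                                                .data$xf_adapted,
                                                .data$ef_hc20),
      cf_adapted_hc50 = characterization_factor(.data$ff_adapted,
                                                .data$xf_adapted,
                                                .data$ef_hc50)
    ) |>
    dplyr::select("cas", "cf_usetox_hc20", "cf_usetox_hc50",
                  "cf_adapted_hc20", "cf_adapted_hc50",
                  "ef_hc20", "ef_hc50", "ff_standard", "xf_standard",
                  "ff_adapted", "xf_adapted")
}

#' Run the full four-methodology characterization
#'
#' Convenience wrapper: effect factors from the harmonized dataset, fate and
#' exposure for both variants, CF assembly.
#'
#' @param chemicals Chemical-property tibble (`cas`, `log_kow`, `koc`,
#'   `kdeg_water`, optionally `kaw`).
#' @param harmonized Harmonized records or `pfas_harmonization` object.
#' @param factors Extrapolation-factor table.
#' @param landscape Landscape list.
#' @return List with elements `efs`, `fate`, `cfs`.
#' @export
run_methodologies <- function(chemicals, harmonized,
                              factors = default_extrapolation_factors(),
                              landscape = default_landscape()) {
  efs <- compute_effect_factors(harmonized, factors)
  fate <- compute_fate_exposure(chemicals, "both", landscape)
  list(efs = efs, fate = fate, cfs = assemble_cfs(efs, fate))
}

#' Pairwise regression of two positive-valued factor sets in log10 space
#'
#' Both series are log10-transformed, then the Pearson correlation, the
#' least-squares regression of `log10(y)` on `log10(x)`, its root mean
#' square error (residual standard error, n - 2 denominator), the sample
#' covariance, and a 95% confidence interval on r via the Fisher
#' z-transform (standard error `1/sqrt(n - 3)`) are computed. Pairs with a
#' missing or non-positive member are dropped.
#'
#' @param x,y Positive numeric vectors, paired (same chemical order).
#' @return List of class `log_regression`: `n`, `r`, `r2`, `rmse`,
#'   `covariance`, `ci_low`, `ci_high`, `slope`, `intercept`.
#' @export
log_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y) & x > 0 & y > 0
  lx <- log10(x[ok]); ly <- log10(y[ok])
  n <- length(lx)
  if (n < 3L) stop("log_regression needs at least 3 complete positive pairs")
  r <- stats::cor(lx, ly)
  fit <- stats::lm(ly ~ lx)
  rmse <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  structure(
    list(n = n, r = r, r2 = r^2, rmse = rmse,
         covariance = stats::cov(lx, ly),
         ci_low = tanh(z - stats::qnorm(0.975) * se),
         ci_high = tanh(z + stats::qnorm(0.975) * se),
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1])),
    class = "log_regression"
  )
}

#' @export
print.log_regression <- function(x, ...) {
  cat(sprintf(
    "log10 regression (n = %d): r = %.3f [%.3f, %.3f], R2 = %.3f, RMSE = %.3f, cov = %.3f\n",
    x$n, x$r, x$ci_low, x$ci_high, x$r2, x$rmse, x$covariance))
  invisible(x)
}

#' Group a per-chemical quantity by number of perfluorinated carbons
#'
#' One row per distinct perfluorinated-carbon count, ordered descending:
#' group size, mean, sample standard deviation (absent for singleton
#' groups), minimum and maximum of the supplied (already log10-transformed)
#' quantity.
#'
#' @param log10_values Numeric per-chemical values (log10 scale).
#' @param n_pfc Integer per-chemical perfluorinated-carbon counts, paired
#'   with `log10_values`.
#' @return Tibble: `n_pfc`, `count`, `mean`, `sd`, `min`, `max`.
#' @export
group_by_pfc <- function(log10_values, n_pfc) {
  ok <- !is.na(log10_values) & !is.na(n_pfc)
  if (!any(ok)) {
    return(tibble::tibble(n_pfc = integer(), count = integer(),
                          mean = numeric(), sd = numeric(),
                          min = numeric(), max = numeric()))
  }
  tibble::tibble(n_pfc = n_pfc[ok], value = log10_values[ok]) |>
    dplyr::group_by(.data$n_pfc) |>
    dplyr::summarise(
      count = dplyr::n(),
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1L) stats::sd(.data$value) else NA_real_,
      min = min(.data$value),
      max = max(.data$value),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_pfc))
}
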