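#' Default freshwater landscape parameters
#'
#' Consensus-model-typical values for a single well-mixed freshwater
#' compartment: suspended solids 15 mg/L, dissolved organic carbon 5 mg/L,
#' biota 1 mg/L, depth 2.5 m, hydraulic residence time 20 days, net
#' sedimentation 2.5e-3 m/day, organic-carbon fraction of suspended solids
#' 0.1. Volatilization is off by default (PFAS anions are effectively
#' non-volatile); when enabled, a two-film model with water-side and air-side
#' mass-transfer coefficients `kl_water` and `kg_air` (m/day) is used.
#'
#' @param ... Named overrides of individual parameters.
#' @return Named list of landscape parameters.
#' @export
default_landscape <- function(...) {
  base <- list(
    suspended_solids = 1.5e-5,       # kg/L
    doc = 5e-6,                      # kg/L
    biota = 1e-6,                    # kg/L
    water_depth = 2.5,               # m
    water_residence_time = 20,       # day
    net_sedimentation_rate = 2.5e-3, # m/day
    foc_suspended = 0.1,
    volatilization_enabled = FALSE,
    kl_water = 0.24,                 # m/day, water-side film
    kg_air = 24                      # m/day, air-side film
  )
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown landscape parameter(s): ",
                        paste(bad, collapse = ", "))
  utils::modifyList(base, over)
}

#' Partition coefficients for the freshwater compartment
#'
#' Standard variant estimates the organic-carbon partition coefficient from
#' log Kow (`Koc = 10^(0.81 logKow + 0.10)` L/kg) and a fish
#' bioconcentration factor from the Kow regression
#' (`BCF = 10^(0.85 logKow - 0.70)`). The PFAS-adapted variant partitions
#' through the supplied Koc directly and does not use a Kow-based BCF
#' (default BCF 1 L/kg), reflecting that Kow-driven hydrophobic partitioning
#' does not describe surface-active perfluoroalkyl acids.
#'
#' @param log_kow Numeric log10 Kow (standard variant).
#' @param koc Numeric Koc in L/kg (adapted variant).
#' @param variant `"standard"` or `"pfas_adapted"`.
#' @param landscape Landscape list (for `foc_suspended`).
#' @param bcf_adapted BCF (L/kg) used in the adapted variant; default 1.
#' @return Tibble with columns `kp_susp`, `kdoc`, `bcf` (all L/kg); rows are
#'   `NA` where the required property is absent (chemical skipped for this
#'   variant).
#' @export
partition_coefficients <- function(log_kow = NA_real_, koc = NA_real_,
                                   variant = c("standard", "pfas_adapted"),
                                   landscape = default_landscape(),
                                   bcf_adapted = 1) {
  variant <- match.arg(variant)
  if (variant == "standard") {
    koc_est <- 10^(0.81 * log_kow + 0.10)
    tibble::tibble(
      kp_susp = landscape$foc_suspended * koc_est,
      kdoc = 0.08 * koc_est,
      bcf = 10^(0.85 * log_kow - 0.70)
    )
  } else {
    n <- max(length(koc), length(log_kow))
    koc <- rep_len(as.numeric(koc), n)
    tibble::tibble(
      kp_susp = landscape$foc_suspended * koc,
      kdoc = 0.08 * koc,
      bcf = ifelse(is.na(koc), NA_real_, rep_len(bcf_adapted, n))
    )
  }
}

#' Dissolved fraction of a chemical in freshwater (exposure factor)
#'
#' `XF = 1 / (1 + Kp*C_susp + Kdoc*C_doc + BCF*C_bio)` with phase
#' concentrations in kg/L and coefficients in L/kg; always in (0, 1].
#'
#' @param kp_susp,kdoc,bcf Partition coefficients (L/kg).
#' @param landscape Landscape list supplying the phase concentrations.
#' @return Numeric dissolved fraction.
#' @export
dissolved_fraction <- function(kp_susp, kdoc, bcf,
                               landscape = default_landscape()) {
  1 / (1 + kp_susp * landscape$suspended_solids +
         kdoc * landscape$doc + bcf * landscape$biota)
}

#' First-order removal rates from the freshwater compartment
#'
#' Degradation uses the supplied water-phase rate; advection is the inverse
#' hydraulic residence time; net sedimentation removes only the
#' particle-bound fraction `(1 - XF)`; volatilization (optional) removes the
#' dissolved fraction through a two-film air-water exchange velocity
#' `1 / (1/kl + 1/(kg * Kaw))`.
#'
#' @param kdeg_water Degradation rate in water (1/day).
#' @param xf Dissolved fraction.
#' @param kaw Dimensionless air-water partition constant (may be `NA`).
#' @param landscape Landscape list.
#' @return Named list of rates (1/day): `deg`, `adv`, `sed`, `volat`.
#' @export
removal_rates <- function(kdeg_water, xf, kaw = NA_real_,
                          landscape = default_landscape()) {
  k_volat <- 0
  if (isTRUE(landscape$volatilization_enabled) && !is.na(kaw) && kaw > 0) {
    v_exch <- 1 / (1 / landscape$kl_water + 1 / (landscape$kg_air * kaw))
    k_volat <- xf * v_exch / landscape$water_depth
  }
  list(
    deg = kdeg_water,
    adv = 1 / landscape$water_residence_time,
    sed = (1 - xf) * landscape$net_sedimentation_rate /
      landscape$water_depth,
    volat = k_volat
  )
}

#' Fate factor as inverse total removal rate
#'
#' For a single well-mixed compartment the steady-state residence time is
#' `FF = 1 / sum(k)` days.
#'
#' @param rates Named list or numeric vector of first-order rates (1/day).
#' @return FF in days.
#' @export
fate_factor_closed_form <- function(rates) {
  total <- sum(unlist(rates))
  if (total <= 0) stop("total removal rate must be positive (infinite residence time)")
  1 / total
}

#' Fate factor matrix from a first-order rate matrix
#'
#' For a multimedia system `dm/dt = K m + e`, the steady-state fate factor
#' matrix is `FF = -K^{-1}`: element (i, j) is the mass residence time in
#' compartment i per unit emission rate into compartment j. With a single
#' compartment this reduces exactly to [fate_factor_closed_form()].
#'
#' @param K Square rate matrix (1/day): diagonal entries are negative total
#'   removal (losses plus transfers out), off-diagonal entries are transfer
#'   rates in.
#' @return Matrix of fate factors (days).
#' @export
fate_factor_matrix <- function(K) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == ncol(K))
  det_K <- det(K)
  if (!is.finite(det_K) || abs(det_K) < .Machine$double.xmin)
    stop("rate matrix is singular")
  -solve(K)
}

#' Fate and exposure factors for a table of chemicals
#'
#' Runs partitioning, dissolved fraction, removal rates and the closed-form
#' fate factor per chemical and requested model variant. Chemicals missing
#' the property a variant requires (log Kow for standard, Koc for
#' PFAS-adapted) are omitted from that variant's rows.
#'
#' @param chemicals Tibble with columns `cas`, `log_kow`, `koc`,
#'   `kdeg_water`; optionally `kaw`, `pka_class`.
#' @param variant `"standard"`, `"pfas_adapted"`, or `"both"`.
#' @param landscape Landscape list.
#' @param bcf_adapted BCF used in the adapted variant (L/kg).
#' @return Tibble: `cas`, `variant`, `kp_susp`, `kdoc`, `bcf`, `xf`,
#'   `k_deg`, `k_adv`, `k_sed`, `k_volat`, `ff_days`.
#' @export
compute_fate_exposure <- function(chemicals,
                                  variant = c("standard", "pfas_adapted", "both"),
                                  landscape = default_landscape(),
                                  bcf_adapted = 1) {
  variant <- match.arg(variant)
  if (variant == "both") {
    return(dplyr::bind_rows(
      compute_fate_exposure(chemicals, "standard", landscape, bcf_adapted),
      compute_fate_exposure(chemicals, "pfas_adapted", landscape, bcf_adapted)
    ))
  }
  chem <- tibble::as_tibble(chemicals)
  if (is.null(chem$kaw)) chem$kaw <- NA_real_
  pc <- partition_coefficients(chem$log_kow, chem$koc, variant, landscape,
                               bcf_adapted)
  xf <- dissolved_fraction(pc$kp_susp, pc$kdoc, pc$bcf, landscape)
  rows <- purrr::map(seq_len(nrow(chem)), function(i) {
    if (is.na(xf[i])) return(NULL)
    k <- removal_rates(chem$kdeg_water[i], xf[i], chem$kaw[i], landscape)
    tibble::tibble(
      cas = chem$cas[i], variant = variant,
      kp_susp = pc$kp_susp[i], kdoc = pc$kdoc[i], bcf = pc$bcf[i],
      xf = xf[i],
      k_deg = k$deg, k_adv = k$adv, k_sed = k$sed, k_volat = k$volat,
      ff_days = fate_factor_closed_form(k)
    )
  })
  dplyr::bind_rows(rows)
}
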