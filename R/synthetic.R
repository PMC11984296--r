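atomic_masses <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007,
                   F = 18.998, S = 32.06)

pfas_head_groups <- function() {
  tibble::tribble(
    ~head,         ~smiles_tail,     ~formula_add,                  ~pka_class,
    "carboxylate", "C(=O)O",         list(C = 1, O = 2, H = 1),     "acid",
    "sulfonate",   "S(=O)(=O)O",     list(S = 1, O = 3, H = 1),     "acid",
    "ethanol",     "CCO",            list(C = 2, H = 5, O = 1),     "neutral",
    "amide",       "C(=O)N",         list(C = 1, O = 1, N = 1, H = 2), "neutral"
  )
}

synthetic_cas <- function(i) {
  body <- sprintf("%05d%02d", 10000 + i, (i * 37) %% 100)
  d <- as.integer(strsplit(body, "")[[1]])
  check <- sum(d * rev(seq_along(d))) %% 10L
  paste0(substr(body, 1, 5), "-", substr(body, 6, 7), "-", check)
}

#' Generate a synthetic PFAS chemical table with known ground truth
#'
#' Builds perfluoroalkyl structures from the template CF3-(CF2)k-X with
#' chain length k in 0..16 and head group X among carboxylate, sulfonate,
#' ethanol and amide, so every molecule carries at least one saturated CF2
#' or CF3 unit and the true perfluorinated-carbon count is k + 1 by
#' construction. Physicochemical properties are sampled from ranges typical
#' of the class: log Kow ~ U(1, 7), Koc ~ 10^N(3, 1) L/kg, degradation rate
#' log-uniform on (1e-4, 1e-1) 1/day (PFAS are persistent); molecular
#' weight is computed from the molecular formula. Deterministic under
#' `seed`.
#'
#' @param n Number of chemicals (>= 1).
#' @param seed Integer seed.
#' @return List with `chemicals` (tibble: `cas`, `smiles`, `mw`, `log_kow`,
#'   `koc`, `kaw`, `kdeg_water`, `pka_class`, `property_provenance`) and
#'   `truth` (tibble: `cas`, `n_pfc`, `chain_k`, `head`).
#' @export
generate_pfas_chemicals <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  set_rng(seed)
  heads <- pfas_head_groups()
  k <- sample(0:16, n, replace = TRUE)
  hi <- sample(nrow(heads), n, replace = TRUE)
  smiles <- character(n)
  mw <- numeric(n)
  for (i in seq_len(n)) {
    smiles[i] <- paste0("FC(F)(F)", strrep("C(F)(F)", k[i]),
                        heads$smiles_tail[hi[i]])
    counts <- c(C = k[i] + 1, F = 2 * k[i] + 3)
    for (el in names(heads$formula_add[[hi[i]]]))
      counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) +
        heads$formula_add[[hi[i]]][[el]]
    mw[i] <- sum(atomic_masses[names(counts)] * unlist(counts))
  }
  cas <- vapply(seq_len(n), synthetic_cas, character(1))
  chemicals <- tibble::tibble(
    cas = cas,
    smiles = smiles,
    mw = mw,
    log_kow = stats::runif(n, 1, 7),
    koc = 10^stats::rnorm(n, 3, 1),
    kaw = NA_real_,
    kdeg_water = 10^stats::runif(n, -4, -1),
    pka_class = heads$pka_class[hi],
    property_provenance = "estimated"
  )
  # perfluorinated-carbon truth follows the structure: all k+1 chain carbons
  # qualify when the head is carbon-linked; the sulfonate head bonds sulfur
  # to the alpha carbon, which then carries a non-fluorine heteroatom and
  # does not count
  n_pfc <- k + 1L - as.integer(heads$head[hi] == "sulfonate")
  truth <- tibble::tibble(cas = cas, n_pfc = n_pfc, chain_k = k,
                          head = heads$head[hi])
  list(chemicals = chemicals, truth = truth)
}

#' Default design for the synthetic ecotoxicity exports
#'
#' Eight species with three test results each per chemical, a
#' between-species SSD spread of 0.7 log10 units around a chemical-specific
#' median drawn uniformly on log10(mg/L) in (-2, 2), within-species
#' measurement noise of 0.2 log10 units, an endpoint mix spanning all six
#' endpoint-regime combinations, and 10% of records corrupted (mutually
#' exclusively) so that each corrupted record is dropped by harmonization
#' for exactly its intended reason. `duplicate_rate` appends byte-identical
#' copies of clean records.
#'
#' @param ... Named overrides.
#' @return Named list describing the design.
#' @export
default_ecotox_design <- function(...) {
  base <- list(
    n_species = 8,
    points_per_species = 3,
    ssd_mu_range = c(-2, 2),     # log10 mg/L
    ssd_sigma = 0.7,             # log10 units, between species
    sigma_within = 0.2,          # log10 units, within species
    endpoint_mix = c(EC10_chronic = 0.25, EC50_chronic = 0.15,
                     NOEC_chronic = 0.20, EC10_acute = 0.10,
                     EC50_acute = 0.20, NOEC_acute = 0.10),
    corruption_rates = c(unreliable = 0.03, bad_qualifier = 0.02,
                         unmapped_species = 0.02, bad_unit = 0.01,
                         missing_value = 0.01, no_cas = 0.01),
    duplicate_rate = 0.02,
    offunit_rate = 0.15,         # benign unit variation (ug/L, g/m3)
    comptox_fraction = 0.5
  )
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("unknown design parameter(s): ",
                        paste(bad, collapse = ", "))
  utils::modifyList(base, over)
}

#' Generate raw ecotoxicity exports with known ground truth
#'
#' For each chemical, species-level true chronic EC10-equivalent
#' sensitivities are drawn from the lognormal SSD `10^N(mu_i, sigma)`; the
#' drawn species sensitivities define the chemical's true HC20/HC50 (test
#' noise on top of them is measurement error, so pipeline recovery is
#' measured against the species actually present, not against the
#' distribution the species were sampled from). Individual test records add
#' lognormal within-species noise and are emitted as EC10/EC50/NOEC,
#' acute/chronic variants by exact inversion of the extrapolation-factor
#' table, making extrapolation a bias-free round trip. Corruptions are
#' mutually exclusive per record and tagged with their intended
#' harmonization drop reason; duplicated records are appended copies.
#'
#' @param chemicals Chemical tibble from [generate_pfas_chemicals()].
#' @param design Design list from [default_ecotox_design()].
#' @param seed Integer seed.
#' @param factors Extrapolation-factor table the generator inverts.
#' @return List: `records` (raw-export tibble ready for [harmonize()]),
#'   `truth` with `chemicals` (per-chemical `ssd_mu`, `ssd_sigma`,
#'   `hc20_true`, `hc50_true` from the realized species draws),
#'   `species` (per-species true EC10eq), and `records` (per raw record
#'   `intended_drop`: a drop reason or `"clean"`).
#' @export
generate_ecotox_records <- function(chemicals,
                                    design = default_ecotox_design(),
                                    seed = 1L,
                                    factors = default_extrapolation_factors()) {
  set_rng(seed + 1L)
  mapping <- species_map()
  mapped_names <- mapping$scientific_name[!duplicated(mapping$common_name)]
  thresholds <- default_chronic_thresholds()
  ep_names <- names(design$endpoint_mix)
  ep_split <- strsplit(ep_names, "_")
  corr_names <- names(design$corruption_rates)
  corr_cum <- cumsum(design$corruption_rates)

  rec_list <- list()
  truth_chem <- list()
  truth_species <- list()
  rid0 <- 0L

  for (ci in seq_len(nrow(chemicals))) {
    cas <- chemicals$cas[ci]
    mu_i <- stats::runif(1, design$ssd_mu_range[1], design$ssd_mu_range[2])
    sp_names <- sample(mapped_names, design$n_species)
    sp <- map_species(sp_names, mapping)
    s_log10 <- stats::rnorm(design$n_species, mu_i, design$ssd_sigma)
    s_ec10eq <- 10^s_log10

    mu_real <- mean(s_log10)
    sigma_real <- if (design$n_species > 1) stats::sd(s_log10) else 0
    truth_chem[[ci]] <- tibble::tibble(
      cas = cas, ssd_mu = mu_real, ssd_sigma = sigma_real,
      hc20_true = hc20(mu_real, sigma_real),
      hc50_true = hc50(2 * s_ec10eq)
    )
    truth_species[[ci]] <- tibble::tibble(
      cas = cas, species_name = sp_names,
      species_group = sp$species_group, ec10eq_true = s_ec10eq
    )

    # one block of n_species * points_per_species records, vectorized
    m <- design$n_species * design$points_per_species
    si <- rep(seq_len(design$n_species), each = design$points_per_species)
    thr <- thresholds[sp$species_group[si]]
    ep_i <- sample(length(ep_names), m, replace = TRUE,
                   prob = design$endpoint_mix)
    endpoint <- vapply(ep_split[ep_i], `[`, "", 1)
    regime <- vapply(ep_split[ep_i], `[`, "", 2)
    mult <- extrapolate(1, endpoint, regime, factors, "ec10eq")
    value <- s_ec10eq[si] * 10^stats::rnorm(m, 0, design$sigma_within) / mult
    unit <- rep("mg/L", m)
    u <- stats::runif(m)
    micro <- u < design$offunit_rate / 2
    value[micro] <- value[micro] * 1000
    unit[micro] <- "ug/L"
    unit[!micro & u < design$offunit_rate] <- "g/m3"
    dur_u <- stats::runif(m, 0.1, 0.9)
    dur_days <- ifelse(regime == "chronic", thr * (1 + dur_u), thr * dur_u)
    in_hours <- stats::runif(m) < 0.5
    duration_value <- ifelse(in_hours, dur_days * 24, dur_days)
    duration_unit <- ifelse(in_hours, "h", "d")
    source <- ifelse(stats::runif(m) < design$comptox_fraction,
                     "COMPTOX", "REACH")
    reliability <- ifelse(source == "REACH",
                          as.character(sample(1:2, m, replace = TRUE)),
                          "pass")
    rec <- tibble::tibble(
      raw_id = sprintf("syn%07d", rid0 + seq_len(m)),
      cas = cas, source = source,
      species_name_raw = sp_names[si],
      endpoint_raw = endpoint,
      qualifier = "=",
      value = value, unit = unit,
      duration_value = duration_value, duration_unit = duration_unit,
      reliability = reliability,
      intended_drop = "clean"
    )
    rid0 <- rid0 + m

    # mutually exclusive corruptions from one uniform draw per record
    u2 <- stats::runif(m)
    hit <- findInterval(u2, c(0, corr_cum), left.open = TRUE)
    for (j in which(hit >= 1 & hit <= length(corr_names))) {
      why <- corr_names[hit[j]]
      rec$intended_drop[j] <- why
      if (why == "unreliable") {
        rec$reliability[j] <- if (rec$source[j] == "REACH")
          as.character(sample(3:4, 1)) else "fail"
      } else if (why == "bad_qualifier") {
        rec$qualifier[j] <- sample(c(">", "<", ">="), 1)
      } else if (why == "unmapped_species") {
        rec$species_name_raw[j] <- paste("Unknownus specius", rec$raw_id[j])
      } else if (why == "bad_unit") {
        rec$unit[j] <- "mol/kg"
      } else if (why == "missing_value") {
        rec$value[j] <- NA_real_
      } else if (why == "no_cas") {
        rec$cas[j] <- "not-a-cas"
      }
    }

    # append byte-identical copies of clean records (dedup drops the copy)
    dup_pick <- which(rec$intended_drop == "clean" &
                        stats::runif(m) < design$duplicate_rate)
    if (length(dup_pick)) {
      dup <- rec[dup_pick, ]
      dup$raw_id <- sprintf("syn%07d", rid0 + seq_along(dup_pick))
      dup$intended_drop <- "duplicate"
      rid0 <- rid0 + length(dup_pick)
      rec <- dplyr::bind_rows(rec, dup)
    }
    rec_list[[ci]] <- rec
  }

  records <- dplyr::bind_rows(rec_list)
  intent <- records[, c("raw_id", "intended_drop")]
  records$intended_drop <- NULL
  list(
    records = records,
    truth = list(
      chemicals = dplyr::bind_rows(truth_chem),
      species = dplyr::bind_rows(truth_species),
      records = intent
    )
  )
}

set_rng <- function(seed) {
  set.seed(as.integer(seed))
}
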