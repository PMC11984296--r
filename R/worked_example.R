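#' Bundled worked example: three chemicals, twenty raw records
#'
#' A fixed miniature dataset exercising every harmonization drop reason and
#' both effect-factor pools, with outputs small enough to verify by hand:
#'
#' * Chemical A (perfluorobutanoic acid, 375-22-4): one usable chronic EC10
#'   of 1 mg/L, so HC20 = 1e-3 kg/m3 and EF(HC20) = 200 exactly.
#' * Chemical B (perfluorooctanoic acid, 335-67-1): three species at 0.1, 1
#'   and 10 mg/L chronic EC10, so the SSD has mu = 0, sigma = 1.
#' * Chemical C (perfluorooctane sulfonic acid, 1763-23-1): a mixed pool
#'   with acute/NOEC extrapolation, a microgram-unit record, and one record
#'   for each drop reason.
#'
#' @return List with `raw` (20 raw records), `chemicals` (property table)
#'   and `expected` (hand-checked harmonization counts).
#' @export
generate_worked_example <- function() {
  chemicals <- tibble::tibble(
    cas = c("375-22-4", "335-67-1", "1763-23-1"),
    smiles = c(
      "FC(F)(F)C(F)(F)C(F)(F)C(=O)O",
      "FC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(=O)O",
      "FC(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)S(=O)(=O)O"
    ),
    mw = c(214.04, 414.07, 500.13),
    log_kow = c(2, 4, 5),
    koc = c(100, 1000, 3000),
    kaw = NA_real_,
    kdeg_water = c(0.05, 0.001, 1e-4),
    pka_class = "acid",
    property_provenance = "experimental"
  )

  r <- function(id, cas, source, sp, ep, q, v, u, dv, du, rel)
    tibble::tibble(raw_id = id, cas = cas, source = source,
                   species_name_raw = sp, endpoint_raw = ep, qualifier = q,
                   value = v, unit = u, duration_value = dv,
                   duration_unit = du, reliability = rel)

  raw <- dplyr::bind_rows(
    # chemical A
    r("A01", "375-22-4", "REACH", "Danio rerio", "EC10", "=", 1.0, "mg/L", 28, "d", "1"),
    r("A02", "375-22-4", "REACH", "Danio rerio", "EC10", "=", 1.2, "mg/L", 28, "d", "3"),
    r("A03", "375-22-4", "COMPTOX", "Daphnia magna", "EC50", ">", 10, "mg/L", 2, "d", "pass"),
    # chemical B
    r("B01", "335-67-1", "REACH", "Danio rerio", "EC10", "=", 0.1, "mg/L", 28, "d", "2"),
    r("B02", "335-67-1", "REACH", "Daphnia magna", "EC10", "=", 1.0, "mg/L", 21, "d", "1"),
    r("B03", "335-67-1", "COMPTOX", "Raphidocelis subcapitata", "EC10", "=", 10, "mg/L", 3, "d", "pass"),
    r("B04", "335-67-1", "REACH", "Daphnia magna", "EC10", "=", 1.0, "mg/L", 21, "d", "1"),
    r("B05", "335-67-1", "COMPTOX", "Unknownus specius", "EC10", "=", 5, "mg/L", 21, "d", "pass"),
    # chemical C
    r("C01", "1763-23-1", "REACH", "Pimephales promelas", "EC10", "=", 0.5, "mg/L", 672, "h", "1"),
    r("C02", "1763-23-1", "REACH", "Pimephales promelas", "EC10", "=", 0.5, "mg/L", 672, "h", "1"),
    r("C03", "1763-23-1", "COMPTOX", "Daphnia magna", "EC50", "=", 4.0, "mg/L", 48, "h", "pass"),
    r("C04", "1763-23-1", "COMPTOX", "Lemna minor", "EC10", "=", 500, "ug/L", 7, "d", "pass"),
    r("C05", "1763-23-1", "COMPTOX", "Daphnia magna", "EC50", "=", 3.0, "mg/L", 2, "d", "fail"),
    r("C06", "1763-23-1", "REACH", "Danio rerio", "EC10", "<", 0.1, "mg/L", 28, "d", "1"),
    r("C07", "1763-23-1", "REACH", "Specius ignotus", "EC10", "=", 1.0, "mg/L", 28, "d", "1"),
    r("C08", "1763-23-1", "REACH", "Danio rerio", "EC10", "=", 2.0, "mol/kg", 28, "d", "2"),
    r("C09", "1763-23-1", "REACH", "Danio rerio", "EC10", "=", NA, "mg/L", 28, "d", "1"),
    r("C10", "not-a-cas", "REACH", "Danio rerio", "EC10", "=", 1.0, "mg/L", 28, "d", "1"),
    r("C11", "1763-23-1", "REACH", "Danio rerio", "NOEC", "=", 0.25, "mg/L", 21, "d", "2"),
    r("C12", "1763-23-1", "REACH", "Oncorhynchus mykiss", "LC50", "=", 2.0, "mg/L", 4, "d", "2")
  )

  expected <- list(
    n_in = 20L, n_out = 9L,
    drops = c(no_cas = 1L, unreliable = 2L, bad_qualifier = 2L,
              unmapped_species = 2L, missing_duration_policy = 0L,
              bad_unit = 1L, missing_value = 1L, bad_endpoint = 0L,
              duplicate = 2L)
  )
  list(raw = raw, chemicals = chemicals, expected = expected)
}
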