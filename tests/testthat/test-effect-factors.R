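test_that("extrapolation to chronic equivalents follows the factor table", {
  tab <- default_extrapolation_factors()
  # identity multipliers on the diagonal of the convention
  expect_equal(extrapolate(3.7, "EC10", "chronic", tab, "ec10eq"), 3.7)
  expect_equal(extrapolate(3.7, "EC50", "chronic", tab, "ec50eq"), 3.7)
  # acute EC50 4.0 mg/L halves toward chronic EC50eq
  expect_equal(extrapolate(4, "EC50", "acute", tab, "ec50eq"), 2)
  # chronic NOEC passes to EC10eq unchanged
  expect_equal(extrapolate(0.3, "NOEC", "chronic", tab, "ec10eq"), 0.3)
  # missing table entry excludes the record (NA)
  expect_true(is.na(extrapolate(1, "LOEC", "chronic", tab, "ec10eq")))
})

test_that("per-species aggregation takes geometric means per pool", {
  rec <- tibble::tibble(
    cas = "335-67-1",
    species_common = c("zebra danio", "zebra danio", "water flea",
                       "water flea", "water flea"),
    species_group = c("fish", "fish", "crustaceans", "crustaceans",
                      "crustaceans"),
    value_ec10eq = c(0.1, 10, 1, 1, 8),
    value_ec50eq = c(NA, NA, 5, NA, NA)
  )
  agg <- aggregate_species(rec)
  fish <- agg[agg$species_common == "zebra danio", ]
  flea <- agg[agg$species_common == "water flea", ]
  expect_equal(fish$geomean_ec10eq_chronic, 1)        # sqrt(0.1 * 10)
  expect_equal(flea$geomean_ec10eq_chronic, 2)        # (1*1*8)^(1/3)
  expect_equal(flea$geomean_ec50eq_chronic, 5)        # single value
  expect_true(is.na(fish$geomean_ec50eq_chronic))     # empty pool omitted
  expect_equal(fish$n_points, 2L)
})

test_that("SSD fit returns log10 mean and sample sd, sigma 0 for n = 1", {
  fit <- fit_ssd(c(0.1, 1, 10))
  expect_equal(fit$mu, 0)
  expect_equal(fit$sigma, 1)
  single <- fit_ssd(5)
  expect_equal(single$mu, log10(5))
  expect_equal(single$sigma, 0)
  expect_equal(fit_ssd(c(2, 2, 2))$sigma, 0)
  expect_null(fit_ssd(numeric(0)))
})

test_that("hc20 matches the numerical lognormal 20th-percentile oracle", {
  grid <- expand.grid(mu = seq(-3, 3, length.out = 10),
                      sigma = seq(0, 2.5, length.out = 10))
  for (i in seq_len(nrow(grid))) {
    mu <- grid$mu[i]; sigma <- grid$sigma[i]
    oracle_mg_l <- stats::qlnorm(0.2, meanlog = mu * log(10),
                                 sdlog = sigma * log(10))
    expect_equal(hc20(mu, sigma), oracle_mg_l * 1e-3,
                 tolerance = 1e-9)
  }
  # monotonicity: larger sigma lowers HC20
  sig <- seq(0, 3, by = 0.25)
  expect_true(all(diff(hc20(0, sig)) < 0))
})

test_that("hc50 is the cross-species geometric mean in kg/m3", {
  expect_equal(hc50(c(0.1, 10)), 1e-3)
  expect_equal(hc50(5), 5e-3)
  expect_equal(hc50(c(1, 1, 8)), 2e-3)
  expect_true(is.na(hc50(numeric(0))))
})

test_that("effect factors are exact ratios of 0.2 and 0.5 to the HC values", {
  expect_equal(effect_factor_hc20(0.2), 1)
  expect_equal(effect_factor_hc20(1e-3), 200)
  expect_equal(effect_factor_hc50(0.5), 1)
  expect_equal(effect_factor_hc50(1e-3), 500)
  expect_equal(effect_factor_hc50(5e-3), 100)
  expect_error(effect_factor_hc20(-1))
})

test_that("trophic coverage counts producer/consumer levels", {
  expect_equal(trophic_coverage(c("fish", "crustaceans", "algae")),
               list(n_species_groups = 3L, n_trophic_levels = 3))
  expect_equal(trophic_coverage("fish")$n_trophic_levels, 1)
  expect_equal(trophic_coverage(character(0)),
               list(n_species_groups = 0L, n_trophic_levels = 0))
  expect_equal(trophic_coverage(c("algae", "aquatic_plants"))$n_trophic_levels, 1)
  expect_equal(trophic_coverage(c("other"))$n_trophic_levels, 0)
})

test_that("single chronic EC10 chemical takes the sigma = 0 path exactly", {
  rec <- tibble::tibble(
    cas = "375-22-4", species_common = "zebra danio",
    species_group = "fish", endpoint = "EC10", regime = "chronic",
    value_mg_per_L = 3, source = "REACH", raw_id = "x"
  )
  ef <- compute_effect_factors(rec)
  expect_equal(ef$hc20_ec10eq_kg_m3, 3e-3)
  expect_equal(ef$ef_hc20, 0.2 / 3e-3)
  expect_equal(ef$ssd_sigma, 0)
})

test_that("acute-EC50-only data still yield a finite EC10eq effect factor", {
  rec <- tibble::tibble(
    cas = "375-22-4", species_common = "water flea",
    species_group = "crustaceans", endpoint = "EC50", regime = "acute",
    value_mg_per_L = 4, source = "REACH", raw_id = "y"
  )
  ef <- compute_effect_factors(rec)
  expect_equal(ef$hc20_ec10eq_kg_m3, 4 * 0.25 * 1e-3)  # via extrapolation
  expect_true(is.finite(ef$ef_hc20))
  expect_equal(ef$hc50_ec50eq_kg_m3, 2e-3)
})

test_that("EF * HC identities hold to machine precision across a synthetic run", {
  gen <- generate_pfas_chemicals(30, seed = 5)
  eco <- generate_ecotox_records(gen$chemicals, seed = 5)
  efs <- compute_effect_factors(harmonize(eco$records))
  expect_equal(efs$ef_hc20 * efs$hc20_ec10eq_kg_m3,
               rep(0.2, nrow(efs)), tolerance = 1e-14)
  expect_equal(efs$ef_hc50 * efs$hc50_ec50eq_kg_m3,
               rep(0.5, nrow(efs)), tolerance = 1e-14)
  expect_true(all(efs$hc20_ec10eq_kg_m3 <= 10^efs$ssd_mu * 1e-3 + 1e-15))
  expect_true(all(efs$n_trophic_levels <= 3))
})

test_that("scaling all concentrations by c scales HCs by c and EFs by 1/c", {
  rec <- tibble::tibble(
    cas = "335-67-1",
    species_common = c("zebra danio", "water flea", "green algae"),
    species_group = c("fish", "crustaceans", "algae"),
    endpoint = "EC10", regime = "chronic",
    value_mg_per_L = c(0.2, 1.7, 9.3), source = "REACH",
    raw_id = c("a", "b", "c")
  )
  base <- compute_effect_factors(rec)
  for (c_scale in c(0.01, 3, 250)) {
    scaled_rec <- rec
    scaled_rec$value_mg_per_L <- rec$value_mg_per_L * c_scale
    scaled <- compute_effect_factors(scaled_rec)
    expect_equal(scaled$hc20_ec10eq_kg_m3, base$hc20_ec10eq_kg_m3 * c_scale)
    expect_equal(scaled$hc50_ec50eq_kg_m3, base$hc50_ec50eq_kg_m3 * c_scale)
    expect_equal(scaled$ef_hc20, base$ef_hc20 / c_scale)
    expect_equal(scaled$ef_hc50, base$ef_hc50 / c_scale)
  }
})
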