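test_that("reliability screen keeps Klimisch 1-2 and CompTox pass only", {
  cfg <- harmonization_config()
  expect_true(filter_reliability("REACH", "1", cfg))
  expect_true(filter_reliability("REACH", "2", cfg))
  expect_false(filter_reliability("REACH", "3", cfg))
  expect_false(filter_reliability("REACH", "4", cfg))
  expect_false(filter_reliability("REACH", NA, cfg))
  expect_true(filter_reliability("COMPTOX", "pass", cfg))
  expect_true(filter_reliability("COMPTOX", "Pass", cfg))
  expect_false(filter_reliability("COMPTOX", "fail", cfg))
  expect_false(filter_reliability("COMPTOX", NA, cfg))
})

test_that("qualifier screen retains '=' (whitespace-tolerant, absent configurable)", {
  cfg <- harmonization_config()
  expect_true(filter_qualifier("=", cfg))
  expect_true(filter_qualifier(" = ", cfg))
  expect_false(filter_qualifier(">", cfg))
  expect_false(filter_qualifier(">=", cfg))
  expect_true(filter_qualifier(NA, cfg))  # lenient default
  strict <- harmonization_config(strict_qualifier = TRUE)
  expect_false(filter_qualifier(NA, strict))
})

test_that("species mapping is exact, case-insensitive, and never guesses", {
  m <- map_species(c("Danio rerio", "DAPHNIA MAGNA", " lemna minor ",
                     "Unknownus specius", ""))
  expect_equal(m$species_common[1:3],
               c("zebra danio", "water flea", "duckweed"))
  expect_equal(m$species_group[1:3],
               c("fish", "crustaceans", "aquatic_plants"))
  expect_true(all(is.na(m$species_common[4:5])))
})

test_that("durations standardize to days across unit aliases", {
  expect_equal(standardize_duration(96, "h"), 4)
  expect_equal(standardize_duration(2, "wk"), 14)
  expect_equal(standardize_duration(30, "min"), 30 / 1440)
  expect_equal(standardize_duration(3, "days"), 3)
  expect_true(is.na(standardize_duration(1, "fortnight")))
  expect_true(is.na(standardize_duration(-1, "d")))
})

test_that("acute/chronic classification uses group thresholds with >= boundary", {
  expect_equal(classify_regime("fish", 28), "chronic")
  expect_equal(classify_regime("crustaceans", 2), "acute")
  expect_equal(classify_regime("algae", 1), "chronic")      # exactly at threshold
  expect_equal(classify_regime("fish", 20.99), "acute")
  expect_true(is.na(classify_regime("fish", NA)))
})

test_that("effect values standardize to mg/L, molar units only with MW", {
  expect_equal(standardize_value(500, "ug/L"), 0.5)
  expect_equal(standardize_value(500, "µg/L"), 0.5)  # micro sign
  expect_equal(standardize_value(2, "g/m3"), 2)
  expect_equal(standardize_value(1, "ppm"), 1)
  expect_equal(standardize_value(3, "ppb"), 0.003)
  expect_equal(standardize_value(1, "mol/L", mw = 100), 1e5)
  expect_true(is.na(standardize_value(1, "mol/L")))       # no MW supplied
  expect_true(is.na(standardize_value(1, "mol/kg")))
  expect_true(is.na(standardize_value(-1, "mg/L")))
})

test_that("endpoint synonyms consolidate; LOEC rejected unless configured", {
  cfg <- harmonization_config()
  expect_equal(consolidate_endpoint(c("LC50", "IC50", "EC50"), cfg),
               rep("EC50", 3))
  expect_equal(consolidate_endpoint(c("LC10", "EC10"), cfg), rep("EC10", 2))
  expect_equal(consolidate_endpoint(c("NOEC", "NOEL"), cfg), rep("NOEC", 2))
  expect_true(is.na(consolidate_endpoint("LOEC", cfg)))
  loec_cfg <- harmonization_config(loec_as = "EC10")
  expect_equal(consolidate_endpoint("LOEC", loec_cfg), "EC10")
})

test_that("deduplication keys on 6 significant digits and keeps first record", {
  rec <- tibble::tibble(
    cas = "335-67-1", species_common = "zebra danio", endpoint = "EC10",
    regime = "chronic", value_mg_per_L = c(1.0, 1.0000001, 2),
    raw_id = c("a", "b", "c")
  )
  dd <- deduplicate_records(rec)
  expect_equal(dd$n_dropped, 1)
  expect_equal(dd$records$raw_id, c("a", "c"))
  # different endpoint is a different key
  rec$endpoint <- c("EC10", "EC50", "EC10")
  expect_equal(deduplicate_records(rec)$n_dropped, 0)
})

test_that("worked-example fixture yields the engineered audit exactly", {
  we <- generate_worked_example()
  h <- harmonize(we$raw)
  expect_equal(h$audit$n_in, we$expected$n_in)
  expect_equal(h$audit$n_out, we$expected$n_out)
  expect_equal(h$audit$drops[names(we$expected$drops)], we$expected$drops)
  expect_equal(h$audit$n_in, h$audit$n_out + sum(h$audit$drops))
})

test_that("all-clean input is fully retained; all-unreliable drops everything", {
  clean <- clean_raw_block(10)
  h <- harmonize(clean)
  expect_equal(h$audit$n_out, 10L)
  expect_equal(sum(h$audit$drops), 0L)

  bad <- clean
  bad$reliability <- "3"
  h2 <- harmonize(bad)
  expect_equal(h2$audit$n_out, 0L)
  expect_equal(unname(h2$audit$drops["unreliable"]), 10L)
})

test_that("empty input returns empty output with a zeroed audit", {
  h <- harmonize(raw_record()[0, ])
  expect_equal(nrow(h$records), 0L)
  expect_equal(h$audit$n_in, 0L)
  expect_equal(sum(h$audit$drops), 0L)
})

test_that("every harmonized record has positive value, enum endpoint, regime", {
  gen <- generate_pfas_chemicals(20, seed = 7)
  eco <- generate_ecotox_records(gen$chemicals, seed = 7)
  h <- harmonize(eco$records)
  expect_gt(nrow(h$records), 0)
  expect_true(all(h$records$value_mg_per_L > 0))
  expect_true(all(h$records$endpoint %in% c("EC10", "EC50", "NOEC")))
  expect_true(all(h$records$regime %in% c("acute", "chronic")))
  expect_true(all(h$records$species_group %in% species_groups()))
  expect_equal(h$audit$n_in, h$audit$n_out + sum(h$audit$drops))
})

test_that("permuting raw input changes neither audit counts nor retained keys", {
  gen <- generate_pfas_chemicals(10, seed = 3)
  eco <- generate_ecotox_records(gen$chemicals, seed = 3)
  h1 <- harmonize(eco$records)
  set.seed(99)
  perm <- sample(nrow(eco$records))
  h2 <- harmonize(eco$records[perm, ])
  expect_equal(h1$audit$drops, h2$audit$drops)
  key <- function(r) sort(paste(r$cas, r$species_common, r$endpoint,
                                r$regime, signif(r$value_mg_per_L, 6)))
  expect_equal(key(h1$records), key(h2$records))
})

test_that("harmonization is idempotent on its own output", {
  gen <- generate_pfas_chemicals(5, seed = 11)
  eco <- generate_ecotox_records(gen$chemicals, seed = 11)
  h1 <- harmonize(eco$records)
  h2 <- harmonize(harmonized_as_raw(h1$records))
  expect_equal(h2$audit$n_out, h1$audit$n_out)
  expect_equal(sum(h2$audit$drops), 0L)
  expect_equal(
    dplyr::arrange(h2$records[, c("cas", "species_common", "endpoint",
                                  "regime", "value_mg_per_L")],
                   cas, species_common, endpoint, regime, value_mg_per_L),
    dplyr::arrange(h1$records[, c("cas", "species_common", "endpoint",
                                  "regime", "value_mg_per_L")],
                   cas, species_common, endpoint, regime, value_mg_per_L)
  )
})
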