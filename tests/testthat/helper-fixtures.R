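# one clean raw record, overridable field by field
raw_record <- function(...) {
  base <- tibble::tibble(
    raw_id = "r1", cas = "335-67-1", source = "REACH",
    species_name_raw = "Danio rerio", endpoint_raw = "EC10",
    qualifier = "=", value = 1, unit = "mg/L",
    duration_value = 28, duration_unit = "d", reliability = "1"
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# n clean records with distinct values so deduplication never fires
clean_raw_block <- function(n, cas = "335-67-1") {
  dplyr::bind_rows(lapply(seq_len(n), function(i)
    raw_record(raw_id = sprintf("r%03d", i), cas = cas,
               value = 1 + i / 13)))
}

# re-express harmonized records as raw input (for idempotence checks)
harmonized_as_raw <- function(records) {
  tibble::tibble(
    raw_id = records$raw_id, cas = records$cas, source = records$source,
    species_name_raw = species_common_to_scientific(records$species_common),
    endpoint_raw = records$endpoint, qualifier = "=",
    value = records$value_mg_per_L, unit = "mg/L",
    duration_value = ifelse(records$regime == "chronic", 1000, 0.01),
    duration_unit = "d",
    reliability = ifelse(records$source == "REACH", "1", "pass")
  )
}

species_common_to_scientific <- function(common) {
  m <- pfascf::species_map()
  m$scientific_name[match(common, m$common_name)]
}
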