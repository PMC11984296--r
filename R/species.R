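#' Load the bundled species mapping table
#'
#' Maps scientific names (including common synonyms) of standard freshwater
#' test species to a controlled common name and one of nine species groups:
#' fish, crustaceans, algae, insects_spiders, aquatic_plants, molluscs,
#' invertebrates, amphibians, other. Matching downstream is exact,
#' case-insensitive after trimming; unmatched species are dropped, never
#' guessed.
#'
#' @return A tibble with columns `scientific_name`, `common_name`, `group`.
#' @export
species_map <- function() {
  path <- system.file("extdata", "species_map.csv", package = "pfascf")
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(tbl)
}

#' Species groups recognized by the harmonizer
#' @return Character vector of the nine group labels.
#' @export
species_groups <- function() {
  c("fish", "crustaceans", "algae", "insects_spiders", "aquatic_plants",
    "molluscs", "invertebrates", "amphibians", "other")
}

#' Map raw species names to common name and group
#'
#' @param species_name_raw Character vector of free-text species names.
#' @param mapping Mapping table as returned by [species_map()].
#' @return Tibble with columns `species_common`, `species_group`; `NA` rows
#'   for unmatched names (rejection, not an error).
#' @examples
#' map_species(c("Danio rerio", "daphnia magna", "Unknownus specius"))
#' @export
map_species <- function(species_name_raw, mapping = species_map()) {
  key <- tolower(trimws(as.character(species_name_raw)))
  key[!nzchar(key)] <- NA_character_
  idx <- match(key, tolower(mapping$scientific_name))
  tibble::tibble(
    species_common = mapping$common_name[idx],
    species_group = mapping$group[idx]
  )
}

#' Default chronic-duration thresholds (days) per species group
#'
#' Minimum exposure duration for a test to be classed as chronic; shorter
#' tests are acute. Values follow conventional regulatory chronic-test
#' durations (e.g. 21-d Daphnia reproduction is chronic, 96-h fish acute is
#' not) and are fully overridable through the harmonization config.
#'
#' @return Named numeric vector, one entry per species group.
#' @export
default_chronic_thresholds <- function() {
  c(fish = 21, crustaceans = 7, algae = 1, insects_spiders = 7,
    aquatic_plants = 7, molluscs = 7, invertebrates = 7,
    amphibians = 21, other = 7)
}
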