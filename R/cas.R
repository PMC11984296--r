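#' Normalize and validate CAS registry numbers
#'
#' Strips separators and leading zeros, regroups the digits into the
#' canonical `NNNNNN-NN-N` form and verifies the CAS check digit (the last
#' digit must equal the weighted digit sum of the preceding digits, weights
#' increasing from right to left, modulo 10).
#'
#' @param x Character vector of putative CAS numbers (with or without
#'   hyphens, possibly zero-padded).
#' @return Character vector of the same length: the canonical CAS string, or
#'   `NA` where the input is malformed or fails the check digit. Rejection is
#'   a value, not an error, so callers can count excluded records.
#' @examples
#' normalize_cas(c("335-67-1", "0000335671", "335-67-2", ""))
#' @export
normalize_cas <- function(x) {
  vapply(as.character(x), normalize_cas_one, character(1), USE.NAMES = FALSE)
}

normalize_cas_one <- function(x) {
  if (is.na(x)) return(NA_character_)
  digits <- gsub("[^0-9]", "", x)
  digits <- sub("^0+", "", digits)
  # CAS: 2-7 leading digits, 2 middle digits, 1 check digit
  if (nchar(digits) < 5L || nchar(digits) > 10L) return(NA_character_)
  d <- as.integer(strsplit(digits, "")[[1]])
  n <- length(d)
  check <- d[n]
  body <- d[seq_len(n - 1L)]
  weights <- rev(seq_along(body))
  if (sum(body * weights) %% 10L != check) return(NA_character_)
  paste0(
    substr(digits, 1L, n - 3L), "-",
    substr(digits, n - 2L, n - 1L), "-",
    substr(digits, n, n)
  )
}
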