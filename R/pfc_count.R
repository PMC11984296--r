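#' Count perfluorinated carbons in a molecule
#'
#' A carbon is perfluorinated when it carries at least one fluorine and its
#' substituents other than carbon are exclusively fluorine — no hydrogens
#' (explicit or implicit) and no other heteroatoms on that carbon. This
#' matches the CF, CF2 and CF3 units of a perfluoroalkyl chain: the carboxyl
#' carbon of PFOA does not count (it bears oxygens), the CF3 and six CF2
#' carbons do. Aromatic ring carbons bearing only carbon neighbours plus one
#' fluorine satisfy the rule and are counted.
#'
#' SMILES are parsed with ChemmineR/OpenBabel; implicit hydrogens are
#' inferred from the unfilled valence (4 minus the sum of bond orders at the
#' carbon).
#'
#' @param smiles Character vector of SMILES strings.
#' @return Integer vector of perfluorinated-carbon counts.
#' @examples
#' count_perfluorinated_carbons(c("CCO", "C(=O)(O)C(F)(F)F"))
#' @export
count_perfluorinated_carbons <- function(smiles) {
  vapply(as.character(smiles), count_pfc_one, integer(1), USE.NAMES = FALSE)
}

count_pfc_one <- function(smi) {
  if (is.na(smi) || !nzchar(smi)) stop("empty SMILES")
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smi)[[1]]),
    error = function(e) stop("unparseable SMILES: ", smi, call. = FALSE)
  )
  atoms <- sub("_[0-9]+$", "", rownames(ChemmineR::atomblock(sdf)))
  bonds <- ChemmineR::bondblock(sdf)
  if (length(atoms) == 0L) stop("unparseable SMILES: ", smi, call. = FALSE)
  if (is.null(dim(bonds)) || nrow(bonds) == 0L) return(0L)

  n_pfc <- 0L
  for (i in which(atoms == "C")) {
    at_i <- bonds[, 1] == i | bonds[, 2] == i
    if (!any(at_i)) next
    nb <- ifelse(bonds[at_i, 1] == i, bonds[at_i, 2], bonds[at_i, 1])
    orders <- bonds[at_i, 3]
    nb_sym <- atoms[nb]
    has_f <- any(nb_sym == "F")
    only_c_or_f <- all(nb_sym %in% c("C", "F"))
    no_implicit_h <- sum(orders) >= 4
    if (has_f && only_c_or_f && no_implicit_h) n_pfc <- n_pfc + 1L
  }
  n_pfc
}
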