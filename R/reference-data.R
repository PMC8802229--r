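#' Built-in amide proton reference statistics
#'
#' Per-residue reference mean and standard deviation (ppm) for the backbone
#' amide proton (atom `H`) of the 19 amide-bearing standard amino acids
#' (proline has no amide proton). Values are representative of large
#' chemical-shift archive statistics for diamagnetic proteins; they serve as
#' the "stated world" for the synthetic-corpus generator and as an external
#' reference table for Z-scoring. They are not a numerical reproduction of
#' any live statistics page.
#'
#' @return A data frame with columns `residue_type`, `atom_name`, `mean`,
#'   `sd`, `count`, of class `reference_stats`.
#' @export
#' @examples
#' head(default_reference_stats())
default_reference_stats <- function() {
  tab <- data.frame(
    residue_type = c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                     "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "SER", "THR",
                     "TRP", "TYR", "VAL"),
    atom_name = "H",
    mean = c(8.20, 8.23, 8.33, 8.30, 8.39, 8.21, 8.33, 8.33,
             8.25, 8.26, 8.22, 8.18, 8.26, 8.36, 8.28, 8.24,
             8.28, 8.32, 8.28),
    sd   = c(0.60, 0.61, 0.63, 0.58, 0.67, 0.60, 0.60, 0.65,
             0.69, 0.70, 0.65, 0.60, 0.60, 0.72, 0.59, 0.62,
             0.78, 0.73, 0.69),
    count = 100000L,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("reference_stats", "data.frame")
  tab
}

# N/O/S-bound protons of the standard amino acids; every other proton name
# is carbon-bound.  Keys are "RES:ATOM"; "*" residue applies to all types
# (backbone amide and N-terminal protons).
.noncarbon_protons <- local({
  x <- c(
    "*:H" = "N", "*:HN" = "N", "*:H1" = "N", "*:H2" = "N", "*:H3" = "N",
    "ARG:HE" = "N", "ARG:HH11" = "N", "ARG:HH12" = "N",
    "ARG:HH21" = "N", "ARG:HH22" = "N",
    "ASN:HD21" = "N", "ASN:HD22" = "N",
    "GLN:HE21" = "N", "GLN:HE22" = "N",
    "HIS:HD1" = "N", "HIS:HE2" = "N",
    "LYS:HZ" = "N", "LYS:HZ1" = "N", "LYS:HZ2" = "N", "LYS:HZ3" = "N",
    "TRP:HE1" = "N",
    "SER:HG" = "O", "THR:HG1" = "O", "TYR:HH" = "O",
    "CYS:HG" = "S"
  )
  x
})

.standard_residues <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                        "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                        "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Classify protons as carbon-bound
#'
#' The corpus filter excludes entries containing a carbon-bound proton with
#' an extreme chemical shift. Files do not state the bound element, so it is
#' derived from an embedded proton topology of the standard amino acids:
#' every proton is carbon-bound except the backbone/N-terminal amide
#' protons and the side-chain N-, O- and S-bound protons (e.g. ARG HE/HH*,
#' ASN HD2x, GLN HE2x, HIS HD1/HE2, LYS HZ*, TRP HE1, SER HG, THR HG1,
#' TYR HH, CYS HG).
#'
#' @param residue_type three-letter residue code (vectorised).
#' @param atom_name atom name (vectorised); non-proton names return `FALSE`.
#' @return Logical vector: `TRUE` where the atom is a carbon-bound proton.
#'   Protons of residue types outside the standard 20 are treated as
#'   non-carbon-bound with a warning.
#' @export
is_carbon_bound_proton <- function(residue_type, atom_name) {
  residue_type <- toupper(residue_type)
  atom_name <- toupper(atom_name)
  is_h <- grepl("^H", atom_name)
  known <- residue_type %in% .standard_residues
  if (any(is_h & !known)) {
    warnf("residue type(s) %s absent from proton topology; protons treated as non-carbon-bound",
          paste(unique(residue_type[is_h & !known]), collapse = ", "))
  }
  key_res <- paste0(residue_type, ":", atom_name)
  key_any <- paste0("*:", atom_name)
  noncarbon <- key_res %in% names(.noncarbon_protons) |
    key_any %in% names(.noncarbon_protons)
  is_h & known & !noncarbon
}
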