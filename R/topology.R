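# Amino-acid side-chain chemistry needed for wrapper counting, plus the
# van der Waals radii used to inflate atoms into the accessible envelope.
#
# A side-chain carbon counts as a nonpolar CHn group (n = 0..3) when it is
# not covalently bonded to N, O or S.  The qualifying atom names below were
# enumerated by hand from standard amino-acid connectivity; carbons excluded
# by the rule are listed separately so the classification is auditable.
# C-alpha never counts (it is backbone, bonded to N).

.sidechain_nonpolar <- list(
  ALA = "CB",
  ARG = c("CB", "CG"),                         # CD-NE, CZ-(NE,NH1,NH2) excluded
  ASN = "CB",                                  # CG-(OD1,ND2) excluded
  ASP = "CB",                                  # CG-(OD1,OD2) excluded
  CYS = character(0),                          # CB-SG excluded
  GLN = c("CB", "CG"),                         # CD-(OE1,NE2) excluded
  GLU = c("CB", "CG"),                         # CD-(OE1,OE2) excluded
  GLY = character(0),
  HIS = "CB",                                  # CG-ND1, CD2-NE2, CE1-(ND1,NE2) excluded
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD"),                   # CE-NZ excluded
  MET = "CB",                                  # CG-SD, CE-SD excluded
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG"),                         # CD-N excluded
  SER = character(0),                          # CB-OG excluded
  THR = "CG2",                                 # CB-OG1 excluded
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),  # CD1-NE1, CE2-NE1 excluded
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),         # CZ-OH excluded
  VAL = c("CB", "CG1", "CG2")
)

# The strictest reading excludes the hydroxyl/thiol-bearing C-beta of
# Ser/Thr/Cys; setting include_polar_cb = TRUE relaxes that.
.polar_cb_residues <- c("SER", "THR", "CYS")

.water_resnames <- c("HOH", "WAT", "TIP", "TIP3", "SOL")

#' Nonpolar side-chain carbon names for a residue type
#'
#' @param resname 3-letter residue code (case-insensitive)
#' @param include_polar_cb also count the C-beta of Ser/Thr/Cys (bonded to
#'   O/S; excluded by default)
#' @return character vector of atom names (empty for Gly and unknown
#'   residues)
#' @export
nonpolar_carbon_names <- function(resname, include_polar_cb = FALSE) {
  resname <- toupper(resname)
  out <- .sidechain_nonpolar[[resname]]
  if (is.null(out)) return(character(0))
  if (include_polar_cb && resname %in% .polar_cb_residues) out <- c(out, "CB")
  out
}

.vdw_table <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80)

#' Van der Waals radius by element symbol (1.70 for unknown elements)
#' @param element character vector of element symbols
#' @return numeric vector of radii, angstroms
#' @export
vdw_radius <- function(element) {
  r <- .vdw_table[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}
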