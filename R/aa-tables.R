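# Residue-level constant tables used by sequence handling and model editing.

#' @keywords internal
AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
  X = "UNK"
)

#' @keywords internal
AA_ONE <- structure(names(AA_THREE), names = AA_THREE)

#' @keywords internal
AA_LETTERS <- names(AA_THREE)

#' @keywords internal
BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# Canonical side-chain atom order per residue type (wwPDB ordering, heavy
# atoms only).  Model editing keeps the longest common prefix of these
# lists when a template residue is relabelled to the target type.
#' @keywords internal
SIDECHAIN_ATOMS <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2"),
  UNK = character(0)
)

#' Atoms retained when a template residue is relabelled to a target type
#'
#' Implements the side-chain pruning rule used for mixed models: the
#' backbone is always kept, and of the side chain only the longest common
#' prefix of the two residues' canonical atom lists survives (so a PHE
#' aligned to a TYR keeps the ring through CZ but loses OH, and anything
#' aligned to ALA is cut back to CB).  A glycine target keeps no CB.
#'
#' @param template_resid three-letter code of the template residue
#' @param target_resid three-letter code of the target residue
#' @return character vector of atom names to retain
#' @keywords internal
shared_atoms <- function(template_resid, target_resid) {
  a <- SIDECHAIN_ATOMS[[template_resid]]
  b <- SIDECHAIN_ATOMS[[target_resid]]
  if (is.null(a) || is.null(b)) return(BACKBONE_ATOMS)
  k <- 0L
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] != b[i]) break
    k <- i
  }
  c(BACKBONE_ATOMS, if (k > 0L) a[seq_len(k)] else character(0))
}

#' @keywords internal
aa1to3 <- function(x) unname(AA_THREE[strsplit(x, "")[[1]]])

#' @keywords internal
aa3to1 <- function(x) {
  out <- AA_ONE[x]
  out[is.na(out)] <- "X"
  unname(out)
}
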