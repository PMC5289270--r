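## Amino-acid lookup tables shared across the interface descriptors.

## 3-letter -> 1-letter code, 20 standard residues
AA_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

## The 7 amino-acid classes used for interface contact signatures.
AA_CLASS_GROUPS <- list(
  aliphatic = c("V", "I", "M", "C", "L"),
  small     = c("A", "S", "P", "T"),
  glycine   = "G",
  aromatic  = c("Y", "F", "W"),
  basic     = c("K", "R", "H"),
  acidic    = c("D", "E"),
  amide     = c("N", "Q")
)

## Residues counted as hydrophobic for interface hydrophobicity.
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "P", "F", "M", "W", "C")

## van der Waals radii (Angstrom) by element, NACCESS-like values.
VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85)

SASA_PROBE <- 1.4

is_standard_aa <- function(resname) toupper(resname) %in% names(AA_321)

aa_one_letter <- function(resname) unname(AA_321[toupper(resname)])

## class index 1..7 per residue name; NA for nonstandard residues
aa_class <- function(resname) {
  one <- aa_one_letter(resname)
  cls <- rep(NA_integer_, length(one))
  for (k in seq_along(AA_CLASS_GROUPS)) {
    cls[one %in% AA_CLASS_GROUPS[[k]]] <- k
  }
  cls
}
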