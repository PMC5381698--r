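# Fixed per-residue chemistry tables used by contact typing, side-chain
# selection, in-silico truncation and molar-mass computation. Heavy atoms only:
# the structures this package targets carry no hydrogens, so donor/acceptor
# capability is a per-atom lookup, not computed chemistry.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Standard PDB heavy-atom names of each side chain (Gly: none).
SIDECHAIN_ATOMS <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(),
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
  VAL = c("CB", "CG1", "CG2")
)

# N/O atoms able to donate an H-bond (backbone N handled separately; Pro has
# no backbone NH).
SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"),
  ASN = "ND2",
  GLN = "NE2",
  HIS = c("ND1", "NE2"),
  LYS = "NZ",
  SER = "OG",
  THR = "OG1",
  TRP = "NE1",
  TYR = "OH"
)

# N/O atoms able to accept an H-bond (backbone O always accepts).
SIDECHAIN_ACCEPTORS <- list(
  ASN = "OD1",
  ASP = c("OD1", "OD2"),
  GLN = "OE1",
  GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"),
  SER = "OG",
  THR = "OG1",
  TYR = "OH"
)

# Salt bridges: basic side-chain N vs acidic side-chain O.
SALT_BASIC <- list(
  ARG = c("NE", "NH1", "NH2"),
  LYS = "NZ",
  HIS = c("ND1", "NE2")
)
SALT_ACIDIC <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)

# Residues whose side-chain carbons count for hydrophobic C-C contacts.
APOLAR_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "PRO", "PHE", "MET", "TRP")

# Average-isotope residue masses (Da); a residue is the amino acid minus one
# water. One water is added back per chain.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLU = "E",
  GLN = "Q", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

is_sidechain_atom <- function(res_name, atom_name) {
  !(atom_name %in% BACKBONE_ATOMS)
}

sidechain_atoms_of <- function(res_name) {
  SIDECHAIN_ATOMS[[res_name]] %||% character()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
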