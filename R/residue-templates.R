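# Ideal internal-coordinate templates for amino-acid side chains and a small
# table of common rotamers.  Bond lengths (A) and angles (deg) follow
# standard engineered-geometry values; each atom is placed by NeRF from
# three previously placed atoms (a, b, c): bonded to c, angle X-c-b,
# dihedral X-c-b-a.  A dihedral marked with chi = k means "rotamer chi_k
# plus the stated offset"; chi = 0 is a fixed dihedral.

sc_row <- function(atom, a, b, c, bond, ang, dih, chi = 0L) {
  data.frame(atom = atom, a = a, b = b, c = c, bond = bond, ang = ang,
             dih = dih, chi = as.integer(chi), stringsAsFactors = FALSE)
}

SIDECHAIN_ZMAT <- list(
  ALA = NULL,
  GLY = NULL,
  SER = sc_row("OG", "N", "CA", "CB", 1.417, 110.8, 0, 1),
  CYS = sc_row("SG", "N", "CA", "CB", 1.808, 113.8, 0, 1),
  THR = rbind(sc_row("OG1", "N", "CA", "CB", 1.433, 109.6, 0, 1),
              sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, -120, 1)),
  VAL = rbind(sc_row("CG1", "N", "CA", "CB", 1.527, 110.5, 0, 1),
              sc_row("CG2", "N", "CA", "CB", 1.527, 110.5, -122.3, 1)),
  ILE = rbind(sc_row("CG1", "N", "CA", "CB", 1.530, 110.4, 0, 1),
              sc_row("CG2", "N", "CA", "CB", 1.521, 110.5, -122.3, 1),
              sc_row("CD1", "CA", "CB", "CG1", 1.513, 113.8, 0, 2)),
  LEU = rbind(sc_row("CG", "N", "CA", "CB", 1.530, 116.3, 0, 1),
              sc_row("CD1", "CA", "CB", "CG", 1.521, 110.7, 0, 2),
              sc_row("CD2", "CA", "CB", "CG", 1.521, 110.7, 122.6, 2)),
  MET = rbind(sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 0, 1),
              sc_row("SD", "CA", "CB", "CG", 1.803, 112.7, 0, 2),
              sc_row("CE", "CB", "CG", "SD", 1.791, 100.9, 0, 3)),
  # proline ring approximated by fixed endo-pucker dihedrals
  PRO = rbind(sc_row("CG", "N", "CA", "CB", 1.492, 104.5, 28.0, 0),
              sc_row("CD", "CA", "CB", "CG", 1.503, 106.1, -40.0, 0)),
  PHE = rbind(sc_row("CG", "N", "CA", "CB", 1.502, 113.8, 0, 1),
              sc_row("CD1", "CA", "CB", "CG", 1.384, 120.8, 0, 2),
              sc_row("CD2", "CA", "CB", "CG", 1.384, 120.8, 180, 2),
              sc_row("CE1", "CB", "CG", "CD1", 1.382, 121.0, 180, 0),
              sc_row("CE2", "CB", "CG", "CD2", 1.382, 121.0, 180, 0),
              sc_row("CZ", "CG", "CD1", "CE1", 1.378, 120.1, 0, 0)),
  TYR = rbind(sc_row("CG", "N", "CA", "CB", 1.512, 113.9, 0, 1),
              sc_row("CD1", "CA", "CB", "CG", 1.389, 120.8, 0, 2),
              sc_row("CD2", "CA", "CB", "CG", 1.389, 120.8, 180, 2),
              sc_row("CE1", "CB", "CG", "CD1", 1.382, 121.1, 180, 0),
              sc_row("CE2", "CB", "CG", "CD2", 1.382, 121.1, 180, 0),
              sc_row("CZ", "CG", "CD1", "CE1", 1.378, 119.9, 0, 0),
              sc_row("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 180, 0)),
  TRP = rbind(sc_row("CG", "N", "CA", "CB", 1.498, 113.6, 0, 1),
              sc_row("CD1", "CA", "CB", "CG", 1.365, 126.9, 0, 2),
              sc_row("CD2", "CA", "CB", "CG", 1.433, 126.6, 180, 2),
              sc_row("NE1", "CB", "CG", "CD1", 1.374, 110.2, 180, 0),
              sc_row("CE2", "CG", "CD1", "NE1", 1.370, 109.0, 0, 0),
              sc_row("CE3", "CD1", "CG", "CD2", 1.398, 133.9, 180, 0),
              sc_row("CZ2", "CD1", "NE1", "CE2", 1.394, 130.4, 180, 0),
              sc_row("CZ3", "CG", "CD2", "CE3", 1.382, 118.8, 180, 0),
              sc_row("CH2", "NE1", "CE2", "CZ2", 1.368, 117.5, 180, 0)),
  ASP = rbind(sc_row("CG", "N", "CA", "CB", 1.516, 112.6, 0, 1),
              sc_row("OD1", "CA", "CB", "CG", 1.249, 118.4, 0, 2),
              sc_row("OD2", "CA", "CB", "CG", 1.249, 118.4, 180, 2)),
  ASN = rbind(sc_row("CG", "N", "CA", "CB", 1.516, 112.6, 0, 1),
              sc_row("OD1", "CA", "CB", "CG", 1.231, 120.8, 0, 2),
              sc_row("ND2", "CA", "CB", "CG", 1.328, 116.4, 180, 2)),
  GLU = rbind(sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 0, 1),
              sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, 0, 2),
              sc_row("OE1", "CB", "CG", "CD", 1.249, 118.4, 0, 3),
              sc_row("OE2", "CB", "CG", "CD", 1.249, 118.4, 180, 3)),
  GLN = rbind(sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 0, 1),
              sc_row("CD", "CA", "CB", "CG", 1.516, 112.6, 0, 2),
              sc_row("OE1", "CB", "CG", "CD", 1.231, 120.8, 0, 3),
              sc_row("NE2", "CB", "CG", "CD", 1.328, 116.4, 180, 3)),
  LYS = rbind(sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 0, 1),
              sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, 0, 2),
              sc_row("CE", "CB", "CG", "CD", 1.520, 111.3, 0, 3),
              sc_row("NZ", "CG", "CD", "CE", 1.489, 111.9, 0, 4)),
  ARG = rbind(sc_row("CG", "N", "CA", "CB", 1.520, 114.1, 0, 1),
              sc_row("CD", "CA", "CB", "CG", 1.520, 111.3, 0, 2),
              sc_row("NE", "CB", "CG", "CD", 1.461, 112.0, 0, 3),
              sc_row("CZ", "CG", "CD", "NE", 1.329, 124.2, 0, 4),
              sc_row("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0, 0),
              sc_row("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180, 0)),
  HIS = rbind(sc_row("CG", "N", "CA", "CB", 1.492, 113.8, 0, 1),
              sc_row("ND1", "CA", "CB", "CG", 1.380, 122.7, 0, 2),
              sc_row("CD2", "CA", "CB", "CG", 1.354, 131.0, 180, 2),
              sc_row("CE1", "CB", "CG", "ND1", 1.326, 109.3, 180, 0),
              sc_row("NE2", "CB", "CG", "CD2", 1.373, 107.1, 180, 0))
)

# Built-in rotamer table: a few most-populated chi sets per residue, most
# common first.  Values are modal side-chain dihedrals (deg).
ROTAMERS <- list(
  SER = list(c(-65), c(62), c(180)),
  CYS = list(c(-65), c(180), c(62)),
  THR = list(c(-60), c(62), c(180)),
  VAL = list(c(175), c(-60), c(62)),
  ILE = list(c(-65, 170), c(-177, 165), c(-65, -60)),
  LEU = list(c(-65, 175), c(-177, 65), c(-85, 65)),
  MET = list(c(-65, 180, 75), c(-65, -65, -70), c(180, 180, 180)),
  PHE = list(c(-65, 90), c(180, 80), c(62, 90)),
  TYR = list(c(-65, 90), c(180, 80), c(62, 90)),
  TRP = list(c(-65, 95), c(180, -105), c(62, -90)),
  ASP = list(c(-70, -15), c(180, 10), c(62, -15)),
  ASN = list(c(-65, -40), c(180, 30), c(62, -75)),
  GLU = list(c(-65, 180, -10), c(180, 180, 10), c(-65, -65, -40)),
  GLN = list(c(-65, 180, -45), c(180, 180, 0), c(-65, -65, -40)),
  LYS = list(c(-65, 180, 180, 180), c(180, 180, 180, 180),
             c(-65, -170, 180, 180)),
  ARG = list(c(-65, 180, 180, 180), c(180, 180, 65, 85),
             c(-65, -65, 180, 180)),
  HIS = list(c(-65, -70), c(180, 60), c(62, -75))
)

# side-chain carbons/sulfurs regarded as apolar for hydrophobic-contact
# classification (carbons adjacent to N/O are excluded)
APOLAR_ATOMS <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "SD", "CE"),
  PRO = c("CB", "CG", "CD"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  CYS = c("CB", "SG"),
  THR = "CG2", LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
  GLU = c("CB", "CG"), GLN = c("CB", "CG"), ASP = "CB", ASN = "CB",
  HIS = "CB"
)

# aromatic ring atom names (least-squares plane fitting, centroids)
RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA3 <- setNames(names(AA1), AA1)

aa_three <- function(x) {
  x <- toupper(x)
  out <- ifelse(nchar(x) == 1, AA1[x], ifelse(x %in% AA1, x, NA))
  if (any(is.na(out))) stop("unknown amino-acid code: ",
                            paste(x[is.na(out)], collapse = ","))
  unname(out)
}

aa_one <- function(x3) {
  out <- AA3[toupper(x3)]
  if (any(is.na(out))) stop("unknown residue name: ",
                            paste(x3[is.na(out)], collapse = ","))
  unname(out)
}

# element from a generated atom name (names we generate are unambiguous)
element_from_name <- function(name) {
  substr(gsub("^[0-9]", "", name), 1, 1)
}

# formal side-chain charges at neutral pH used by the charge profile
FORMAL_CHARGE <- c(LYS = 1L, ARG = 1L, ASP = -1L, GLU = -1L, HIS = 0L)
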