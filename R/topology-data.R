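## Reduced, self-contained polar-hydrogen parameter set.
##
## The package ships its own internal-coordinate templates (z-matrices),
## partial charges and atom classes for the 20 standard amino acids in a
## united-atom ("polar hydrogen") representation: hydrogens bound to N, O and
## S are explicit, aliphatic and aromatic hydrogens are folded into their
## carbon, which carries an enlarged van der Waals radius.  Values are
## idealized textbook geometry; they are not a redistribution of any force
## field file.  Lennard-Jones radii/epsilons and SASA gammas live in
## inst/extdata/atom_classes.tsv (see load_atom_classes).

## Backbone geometry constants (Angstrom / degrees).
BB <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231,
  b_NH = 1.010, b_CACB = 1.530,
  a_CNCA = 121.7, a_NCAC = 111.2, a_CACN = 116.2, a_OCCA = 120.8,
  a_HNC = 119.8, a_CBCAN = 110.5,
  ## dihedral CB-CA-N-C fixing L-chirality (see tests for the check)
  d_CBCANC = 122.55
)

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

## Helper to build one z-matrix row.
zr <- function(name, a, b, c, bond, angle, tors, chi = NA_integer_,
               element = substr(name, 1, 1), class, charge) {
  data.frame(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
             tors = tors, chi = chi, element = element, class = class,
             charge = charge, stringsAsFactors = FALSE)
}

## Standard CB entry shared by all residues that have one.
zr_cb <- function(class = "CH2", charge = 0)
  zr("CB", "C", "N", "CA", BB$b_CACB, BB$a_CBCAN, BB$d_CBCANC,
     element = "C", class = class, charge = charge)

## Side-chain z-matrices.  Column `tors` is the dihedral X-c-b-a in degrees;
## when `chi` is set the dihedral is chi_k + tors.
SIDECHAIN_ZMAT <- local({
  z <- list()
  z$ALA <- zr_cb("CH3")
  z$ARG <- rbind(
    zr_cb(),
    zr("CG",  "N",  "CA", "CB", 1.52, 114.0, 0, 1L, "C", "CH2", 0),
    zr("CD",  "CA", "CB", "CG", 1.52, 111.3, 0, 2L, "C", "CH2", 0.10),
    zr("NE",  "CB", "CG", "CD", 1.46, 112.0, 0, 3L, "N", "NC", -0.40),
    zr("CZ",  "CG", "CD", "NE", 1.33, 124.2, 0, 4L, "C", "C",   0.50),
    zr("NH1", "CD", "NE", "CZ", 1.33, 120.0, 0,   NA, "N", "NC", -0.45),
    zr("NH2", "CD", "NE", "CZ", 1.33, 120.0, 180, NA, "N", "NC", -0.45),
    zr("HE",  "NH1", "CZ", "NE", 1.01, 118.0, 180, NA, "H", "H", 0.30),
    zr("HH11", "NE", "CZ", "NH1", 1.01, 120.0, 0,  NA, "H", "H", 0.35),
    zr("HH12", "NE", "CZ", "NH1", 1.01, 120.0, 180, NA, "H", "H", 0.35),
    zr("HH21", "NE", "CZ", "NH2", 1.01, 120.0, 0,  NA, "H", "H", 0.35),
    zr("HH22", "NE", "CZ", "NH2", 1.01, 120.0, 180, NA, "H", "H", 0.35))
  z$ASN <- rbind(
    zr_cb(),
    zr("CG",  "N", "CA", "CB", 1.52, 112.6, 0, 1L, "C", "C",  0.55),
    zr("OD1", "CA", "CB", "CG", 1.23, 120.8, 0, 2L, "O", "O", -0.55),
    zr("ND2", "CA", "CB", "CG", 1.33, 116.4, 180, 2L, "N", "NH", -0.60),
    zr("HD21", "OD1", "CG", "ND2", 1.01, 120.0, 180, NA, "H", "H", 0.30),
    zr("HD22", "OD1", "CG", "ND2", 1.01, 120.0, 0,   NA, "H", "H", 0.30))
  z$ASP <- rbind(
    zr_cb(),
    zr("CG",  "N", "CA", "CB", 1.52, 112.6, 0, 1L, "C", "C", 0.20),
    zr("OD1", "CA", "CB", "CG", 1.25, 118.4, 0, 2L, "O", "OC", -0.60),
    zr("OD2", "CA", "CB", "CG", 1.25, 118.4, 180, 2L, "O", "OC", -0.60))
  z$CYS <- rbind(
    zr_cb(charge = 0.10),
    zr("SG", "N", "CA", "CB", 1.81, 114.0, 0, 1L, "S", "S", -0.30),
    zr("HG", "CA", "CB", "SG", 1.34, 96.0, 180, NA, "H", "H", 0.20))
  z$GLN <- rbind(
    zr_cb(),
    zr("CG",  "N", "CA", "CB", 1.52, 114.0, 0, 1L, "C", "CH2", 0),
    zr("CD",  "CA", "CB", "CG", 1.52, 112.6, 0, 2L, "C", "C", 0.55),
    zr("OE1", "CB", "CG", "CD", 1.23, 120.8, 0, 3L, "O", "O", -0.55),
    zr("NE2", "CB", "CG", "CD", 1.33, 116.4, 180, 3L, "N", "NH", -0.60),
    zr("HE21", "OE1", "CD", "NE2", 1.01, 120.0, 180, NA, "H", "H", 0.30),
    zr("HE22", "OE1", "CD", "NE2", 1.01, 120.0, 0,   NA, "H", "H", 0.30))
  z$GLU <- rbind(
    zr_cb(),
    zr("CG",  "N", "CA", "CB", 1.52, 114.0, 0, 1L, "C", "CH2", 0),
    zr("CD",  "CA", "CB", "CG", 1.52, 112.6, 0, 2L, "C", "C", 0.20),
    zr("OE1", "CB", "CG", "CD", 1.25, 118.4, 0, 3L, "O", "OC", -0.60),
    zr("OE2", "CB", "CG", "CD", 1.25, 118.4, 180, 3L, "O", "OC", -0.60))
  z$GLY <- zr("CB", "C", "N", "CA", 1, 1, 0, NA, "C", "CH2", 0)[0, ]
  z$HIS <- rbind(
    zr_cb(),
    zr("CG",  "N", "CA", "CB", 1.50, 113.8, 0, 1L, "C", "CR", 0.10),
    zr("ND1", "CA", "CB", "CG", 1.38, 122.7, 0, 2L, "N", "NH", -0.40),
    zr("CD2", "CA", "CB", "CG", 1.36, 129.7, 180, 2L, "C", "CR", 0.10),
    zr("CE1", "CB", "CG", "ND1", 1.32, 109.3, 180, NA, "C", "CR", 0.30),
    zr("NE2", "CB", "CG", "CD2", 1.37, 107.2, 180, NA, "N", "N", -0.40),
    zr("HD1", "CD2", "CG", "ND1", 1.01, 126.0, 180, NA, "H", "H", 0.30))
  z$ILE <- rbind(
    zr_cb("CH1"),
    zr("CG1", "N", "CA", "CB", 1.53, 110.4, 0, 1L, "C", "CH2", 0),
    zr("CG2", "N", "CA", "CB", 1.53, 110.5, 122, 1L, "C", "CH3", 0),
    zr("CD1", "CA", "CB", "CG1", 1.53, 113.8, 0, 2L, "C", "CH3", 0))
  z$LEU <- rbind(
    zr_cb(),
    zr("CG",  "N", "CA", "CB", 1.53, 116.3, 0, 1L, "C", "CH1", 0),
    zr("CD1", "CA", "CB", "CG", 1.53, 110.5, 0, 2L, "C", "CH3", 0),
    zr("CD2", "CA", "CB", "CG", 1.53, 110.5, 122, 2L, "C", "CH3", 0))
  z$LYS <- rbind(
    zr_cb(),
    zr("CG", "N", "CA", "CB", 1.52, 114.0, 0, 1L, "C", "CH2", 0),
    zr("CD", "CA", "CB", "CG", 1.52, 111.3, 0, 2L, "C", "CH2", 0),
    zr("CE", "CB", "CG", "CD", 1.52, 111.3, 0, 3L, "C", "CH2", 0.25),
    zr("NZ", "CG", "CD", "CE", 1.49, 112.0, 0, 4L, "N", "NC", -0.30),
    zr("HZ1", "CD", "CE", "NZ", 1.01, 109.5, 180, NA, "H", "H", 0.35),
    zr("HZ2", "CD", "CE", "NZ", 1.01, 109.5, 60,  NA, "H", "H", 0.35),
    zr("HZ3", "CD", "CE", "NZ", 1.01, 109.5, -60, NA, "H", "H", 0.35))
  z$MET <- rbind(
    zr_cb(),
    zr("CG", "N", "CA", "CB", 1.52, 114.0, 0, 1L, "C", "CH2", 0.06),
    zr("SD", "CA", "CB", "CG", 1.81, 112.7, 0, 2L, "S", "S", -0.12),
    zr("CE", "CB", "CG", "SD", 1.79, 100.8, 0, 3L, "C", "CH3", 0.06))
  z$PHE <- rbind(
    zr_cb(),
    zr("CG",  "N", "CA", "CB", 1.50, 113.8, 0, 1L, "C", "CR", 0),
    zr("CD1", "CA", "CB", "CG", 1.39, 120.3, 0, 2L, "C", "CR", 0),
    zr("CD2", "CA", "CB", "CG", 1.39, 120.3, 180, 2L, "C", "CR", 0),
    zr("CE1", "CB", "CG", "CD1", 1.39, 120.6, 180, NA, "C", "CR", 0),
    zr("CE2", "CB", "CG", "CD2", 1.39, 120.6, 180, NA, "C", "CR", 0),
    zr("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0, NA, "C", "CR", 0))
  z$PRO <- rbind(
    zr_cb(),
    zr("CG", "N", "CA", "CB", 1.50, 104.5, 30, NA, "C", "CH2", 0),
    zr("CD", "CA", "CB", "CG", 1.51, 106.1, -35, NA, "C", "CH2", 0.10))
  z$SER <- rbind(
    zr_cb(charge = 0.25),
    zr("OG", "N", "CA", "CB", 1.42, 110.8, 0, 1L, "O", "OH", -0.65),
    zr("HG", "CA", "CB", "OG", 0.96, 109.5, 180, NA, "H", "H", 0.40))
  z$THR <- rbind(
    zr_cb("CH1", charge = 0.25),
    zr("OG1", "N", "CA", "CB", 1.43, 109.6, 0, 1L, "O", "OH", -0.65),
    zr("HG1", "CA", "CB", "OG1", 0.96, 109.5, 180, NA, "H", "H", 0.40),
    zr("CG2", "N", "CA", "CB", 1.53, 110.5, -120, 1L, "C", "CH3", 0))
  z$TRP <- rbind(
    zr_cb(),
    zr("CG",  "N", "CA", "CB", 1.50, 113.8, 0, 1L, "C", "CR", 0),
    zr("CD1", "CA", "CB", "CG", 1.37, 126.9, 0, 2L, "C", "CR", 0.15),
    zr("CD2", "CA", "CB", "CG", 1.43, 126.7, 180, 2L, "C", "CR", 0),
    zr("NE1", "CB", "CG", "CD1", 1.38, 110.2, 180, NA, "N", "NH", -0.60),
    zr("CE2", "CB", "CG", "CD2", 1.41, 107.2, 180, NA, "C", "CR", 0.10),
    zr("CE3", "CB", "CG", "CD2", 1.40, 133.9, 0, NA, "C", "CR", 0),
    zr("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, 180, NA, "C", "CR", 0),
    zr("CZ3", "CG", "CD2", "CE3", 1.39, 118.6, 180, NA, "C", "CR", 0),
    zr("CH2", "CD2", "CE2", "CZ2", 1.37, 117.5, 0, NA, "C", "CR", 0),
    zr("HE1", "CG", "CD1", "NE1", 1.01, 125.0, 180, NA, "H", "H", 0.35))
  z$TYR <- rbind(
    zr_cb(),
    zr("CG",  "N", "CA", "CB", 1.51, 113.8, 0, 1L, "C", "CR", 0),
    zr("CD1", "CA", "CB", "CG", 1.39, 120.3, 0, 2L, "C", "CR", 0),
    zr("CD2", "CA", "CB", "CG", 1.39, 120.3, 180, 2L, "C", "CR", 0),
    zr("CE1", "CB", "CG", "CD1", 1.39, 120.6, 180, NA, "C", "CR", 0),
    zr("CE2", "CB", "CG", "CD2", 1.39, 120.6, 180, NA, "C", "CR", 0),
    zr("CZ",  "CG", "CD1", "CE1", 1.39, 120.0, 0, NA, "C", "CR", 0.25),
    zr("OH",  "CD1", "CE1", "CZ", 1.38, 120.0, 180, NA, "O", "OH", -0.65),
    zr("HH",  "CE1", "CZ", "OH", 0.96, 109.5, 180, NA, "H", "H", 0.40))
  z$VAL <- rbind(
    zr_cb("CH1"),
    zr("CG1", "N", "CA", "CB", 1.53, 110.5, 0, 1L, "C", "CH3", 0),
    zr("CG2", "N", "CA", "CB", 1.53, 110.5, 122, 1L, "C", "CH3", 0))
  z
})

## Number of chi angles per residue type (rotatable heavy-atom torsions).
N_CHI <- c(ALA = 0L, ARG = 4L, ASN = 2L, ASP = 2L, CYS = 1L, GLN = 3L,
           GLU = 3L, GLY = 0L, HIS = 2L, ILE = 2L, LEU = 2L, LYS = 4L,
           MET = 3L, PHE = 2L, PRO = 0L, SER = 1L, THR = 1L, TRP = 2L,
           TYR = 2L, VAL = 1L)

## Four-atom name tuples defining each chi angle.
CHI_ATOMS <- list(
  ARG = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","NE"), c("CG","CD","NE","CZ")),
  ASN = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  ASP = list(c("N","CA","CB","CG"), c("CA","CB","CG","OD1")),
  CYS = list(c("N","CA","CB","SG")),
  GLN = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  GLU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","OE1")),
  HIS = list(c("N","CA","CB","CG"), c("CA","CB","CG","ND1")),
  ILE = list(c("N","CA","CB","CG1"), c("CA","CB","CG1","CD1")),
  LEU = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  LYS = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD"),
             c("CB","CG","CD","CE"), c("CG","CD","CE","NZ")),
  MET = list(c("N","CA","CB","CG"), c("CA","CB","CG","SD"),
             c("CB","CG","SD","CE")),
  PHE = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  SER = list(c("N","CA","CB","OG")),
  THR = list(c("N","CA","CB","OG1")),
  TRP = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  TYR = list(c("N","CA","CB","CG"), c("CA","CB","CG","CD1")),
  VAL = list(c("N","CA","CB","CG1"))
)

## Most common rotamer (chi values, degrees) used when side chains are
## rebuilt from scratch, plus the discrete states sampled during
## randomization.
COMMON_ROTAMER <- list(
  ARG = c(-60, 180, 180, 180), ASN = c(-60, -20), ASP = c(-60, -15),
  CYS = c(-60), GLN = c(-60, 180, 0), GLU = c(-60, 180, -10),
  HIS = c(-60, 90), ILE = c(-60, 170), LEU = c(-60, 175),
  LYS = c(-60, 180, 180, 180), MET = c(-60, 180, 75), PHE = c(-60, 90),
  SER = c(-60), THR = c(-60), TRP = c(-60, 90), TYR = c(-60, 90),
  VAL = c(175)
)

CHI1_STATES <- c(-60, 180, 60)
CHI_RING_STATES <- c(90, -90)

## 2-fold symmetric atom-name relabelings per residue type (heavy atoms).
FLIP_PAIRS <- list(
  ASP = list(c("OD1", "OD2")),
  GLU = list(c("OE1", "OE2")),
  PHE = list(c("CD1", "CD2"), c("CE1", "CE2")),
  TYR = list(c("CD1", "CD2"), c("CE1", "CE2")),
  ARG = list(c("NH1", "NH2")),
  LEU = list(c("CD1", "CD2")),
  VAL = list(c("CG1", "CG2"))
)

## Hydrogen-bond donors: (hydrogen, heavy donor) atom name pairs.
HB_DONORS <- list(
  backbone = list(c("H", "N")),
  ARG = list(c("HE", "NE"), c("HH11", "NH1"), c("HH12", "NH1"),
             c("HH21", "NH2"), c("HH22", "NH2")),
  ASN = list(c("HD21", "ND2"), c("HD22", "ND2")),
  GLN = list(c("HE21", "NE2"), c("HE22", "NE2")),
  HIS = list(c("HD1", "ND1")),
  LYS = list(c("HZ1", "NZ"), c("HZ2", "NZ"), c("HZ3", "NZ")),
  SER = list(c("HG", "OG")),
  THR = list(c("HG1", "OG1")),
  TRP = list(c("HE1", "NE1")),
  TYR = list(c("HH", "OH"))
)

## Hydrogen-bond acceptors: (acceptor, acceptor-base) atom name pairs.
HB_ACCEPTORS <- list(
  backbone = list(c("O", "C")),
  ASN = list(c("OD1", "CG")),
  ASP = list(c("OD1", "CG"), c("OD2", "CG")),
  GLN = list(c("OE1", "CD")),
  GLU = list(c("OE1", "CD"), c("OE2", "CD")),
  HIS = list(c("NE2", "CE1")),
  SER = list(c("OG", "CB")),
  THR = list(c("OG1", "CB")),
  TYR = list(c("OH", "CZ"))
)

## Backbone partial charges and classes.
backbone_atoms <- function(resname) {
  if (resname == "PRO") {
    data.frame(name = c("N", "CA", "C", "O"),
               element = c("N", "C", "C", "O"),
               class = c("N", "CH1", "C", "O"),
               charge = c(-0.20, 0.10, 0.55, -0.55),
               stringsAsFactors = FALSE)
  } else {
    ca_class <- if (resname == "GLY") "CH2" else "CH1"
    data.frame(name = c("N", "H", "CA", "C", "O"),
               element = c("N", "H", "C", "C", "O"),
               class = c("NH", "H", ca_class, "C", "O"),
               charge = c(-0.35, 0.25, 0.10, 0.55, -0.55),
               stringsAsFactors = FALSE)
  }
}

## Expected atom count per residue type after the polar-hydrogen build.
residue_atom_count <- function(resname) {
  nb <- if (resname == "PRO") 4L else 5L
  nb + nrow(SIDECHAIN_ZMAT[[resname]])
}

#' Load the packaged atom-class parameter table
#'
#' One atom class per line: class token, van der Waals radius (Rmin/2,
#' Angstrom), Lennard-Jones well depth epsilon (kcal/mol), SASA surface
#' tension gamma (kcal/mol/A^2), HCT descreening scale factor.
#'
#' @param path optional path to an alternative table in the same format.
#' @return data.frame with one row per atom class.
#' @export
load_atom_classes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "atom_classes.tsv", package = "loopcsa")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
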