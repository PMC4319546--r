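## Force-field constants and chemical lookup tables.
##
## All energy parameters live in one place so an alternative parameter
## revision is a config swap, not a code change.

#' AutoDock4.1 bound-state atom-type parameters
#'
#' One row per supported AutoDock atom type: `Rii` (sum of vdW radii at the
#' pair minimum, Angstrom), `eps` (well depth, kcal/mol), `vol` (atomic
#' fragmental solvation volume, Angstrom^3), `solpar` (atomic solvation
#' parameter, kcal/(mol Angstrom^3)), `hbond` (one of `"none"`, `"donor"`,
#' `"acceptor"`), and for acceptors the 12-10 hydrogen-bond minimum position
#' `Rij_hb` (Angstrom) and depth `eps_hb` (kcal/mol).
#'
#' @return A data.frame keyed by the `ad_type` column.
#' @export
ad4_type_params <- function() {
  ## na.strings: "NA" is the acceptor-nitrogen type, not a missing value
  p <- read.table(header = TRUE, stringsAsFactors = FALSE,
                  na.strings = character(0), text = "
ad_type  Rii  eps   vol     solpar   hbond    Rij_hb eps_hb
C        4.00 0.150 33.5103 -0.00143 none     0      0
A        4.00 0.150 33.5103 -0.00052 none     0      0
N        3.50 0.160 22.4493 -0.00162 none     0      0
NA       3.50 0.160 22.4493 -0.00162 acceptor 1.9    5.0
OA       3.20 0.200 17.1573 -0.00251 acceptor 1.9    5.0
SA       4.00 0.200 33.5103 -0.00214 acceptor 2.5    1.0
S        4.00 0.200 33.5103 -0.00214 none     0      0
HD       2.00 0.020  0.0000  0.00051 donor    0      0
H        2.00 0.020  0.0000  0.00051 none     0      0
F        3.09 0.080 15.4480 -0.00110 none     0      0
Cl       4.09 0.276 35.8235 -0.00110 none     0      0
Br       4.33 0.389 42.5661 -0.00110 none     0      0
I        4.72 0.550 55.0585 -0.00110 none     0      0
P        4.20 0.200 38.7924 -0.00110 none     0      0
")
  rownames(p) <- p$ad_type
  p
}

#' Scoring parameters for the AutoDock4.1 semi-empirical force field
#'
#' Term weights (bound-state calibration), the non-bonded cutoff, the
#' pair-distance smoothing width, the desolvation Gaussian width, the
#' charge-dependent solvation increment, the Coulomb conversion constant and
#' the sigmoidal distance-dependent dielectric constants of Mehler and
#' Solmajer.
#'
#' @param nb_cutoff Non-bonded cutoff in Angstrom. Default 8.
#' @param smoothing_width Width of the flat-bottom smoothing applied to the
#'   vdW and hydrogen-bond pair distance, Angstrom. Default 0.5.
#' @param max_energy Short-range per-pair ceiling for the smoothed 12-6 and
#'   12-10 terms, kcal/mol. Default 100.
#' @return A list of constants consumed by the energy functions.
#' @export
scoring_params <- function(nb_cutoff = 8.0, smoothing_width = 0.5,
                           max_energy = 100) {
  list(
    W_vdw  = 0.1662,
    W_hb   = 0.1209,
    W_elec = 0.1406,
    W_sol  = 0.1322,
    nb_cutoff = nb_cutoff,
    smoothing_width = smoothing_width,
    max_energy = max_energy,
    desolv_sigma = 3.6,
    qsolpar = 0.01097,       # charge-dependent solvation increment, per |e|
    coulomb = 332.0636,      # kcal*A/(mol*e^2)
    ms_eps0   = 78.4,        # Mehler-Solmajer sigmoidal dielectric
    ms_A      = -8.5525,
    ms_lambda = 0.003627,
    ms_k      = 7.7839,
    types = ad4_type_params()
  )
}

## Gasteiger-Marsili PEOE electronegativity coefficients chi = a + b*q + c*q^2
## by element and hybridization class.  The cation electronegativity chi+ is
## a+b+c except for hydrogen, where the original calibration uses 20.02.
peoe_coefficients <- function() {
  k <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
class  a     b     c
H      7.17  6.24 -0.56
C.3    7.98  9.18  1.88
C.2    8.79  9.32  1.51
C.1   10.39  9.45  0.73
N.3   11.54 10.82  1.36
N.2   12.87 11.15  0.85
N.1   15.68 11.70 -0.27
O.3   14.18 12.92  1.39
O.2   17.07 13.79  0.47
F     14.66 13.85  2.31
Cl    11.00  9.69  1.35
Br    10.08  8.47  1.16
I      9.90  7.96  0.96
S     10.14  9.13  1.38
P      8.90  8.24  0.96
")
  k$chiplus <- k$a + k$b + k$c
  k$chiplus[k$class == "H"] <- 20.02
  rownames(k) <- k$class
  k
}

## Covalent radii (Angstrom) for distance-based bond perception.
covalent_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20, B = 0.84
)

## Element-based vdW radii (Angstrom) for the steric-clash metric; kept
## independent of AutoDock typing so clashes can be checked on raw models.
element_vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)

## Tolerance added to the covalent-radius sum when inferring bonds.
BOND_TOLERANCE <- 0.45

## Clash definition: non-bonded pair closer than this fraction of the vdW sum.
CLASH_FRACTION <- 0.6

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

WATER_NAMES <- c("HOH", "WAT", "DOD")

## Atom names an alanine residue may carry after truncation.
ALA_ATOMS <- c("N", "CA", "C", "O", "CB", "OXT",
               "H", "H1", "H2", "H3", "HA", "HA2", "HA3", "HXT")

## Side-chain heavy atoms beyond CB, per standard residue; the deletion set
## for alanine truncation and the oracle for mutant atom counts.
SIDECHAIN_BEYOND_CB <- list(
  ALA = character(0),
  GLY = character(0),
  SER = "OG",
  CYS = "SG",
  THR = c("OG1", "CG2"),
  VAL = c("CG1", "CG2"),
  LEU = c("CG", "CD1", "CD2"),
  ILE = c("CG1", "CG2", "CD1"),
  MET = c("CG", "SD", "CE"),
  PRO = c("CG", "CD"),
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  ASP = c("CG", "OD1", "OD2"),
  GLU = c("CG", "CD", "OE1", "OE2"),
  ASN = c("CG", "OD1", "ND2"),
  GLN = c("CG", "CD", "OE1", "NE2"),
  LYS = c("CG", "CD", "CE", "NZ"),
  ARG = c("CG", "CD", "NE", "CZ", "NH1", "NH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)
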