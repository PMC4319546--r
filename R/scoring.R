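## AutoDock4 semi-empirical pairwise interaction energy.
##
## Four weighted terms over receptor-ligand atom pairs within the
## non-bonded cutoff:
##   vdW        A_ij/r^12 - B_ij/r^6       (Lennard-Jones 12-6)
##   H-bond     C_ij/r^12 - D_ij/r^10      (12-10, distance-only)
##   elec       332.0636 q_i q_j / (eps(r) r), eps(r) sigmoidal (Mehler-
##              Solmajer distance-dependent dielectric)
##   desolv     (S_i V_j + S_j V_i) exp(-r^2/(2 sigma^2)), S = solpar +
##              0.01097 |q|
## Pair parameters combine as Rij = (Rii+Rjj)/2, eps_ij = sqrt(eps_i eps_j).
## The 12-6/12-10 pair distance is smoothed toward Rij by up to half the
## smoothing width (flat-bottom well, as in the AutoGrid tables) and the
## ascending branch is capped at `max_energy`. Only the intermolecular
## energy is computed: the pose is fixed, so internal and torsional terms
## cancel in any mutant-minus-wild-type difference.

## Flat-bottom smoothing: move r toward rij by up to width/2.
smooth_r <- function(r, rij, width) {
  half <- width / 2
  out <- r
  out[r > rij + half] <- r[r > rij + half] - half
  out[r < rij - half] <- r[r < rij - half] + half
  out[abs(r - rij) <= half] <- rij[abs(r - rij) <= half]
  out
}

pair_rij_eps <- function(type_i, type_j, params) {
  t <- params$types
  list(rij = (t[type_i, "Rii"] + t[type_j, "Rii"]) / 2,
       eps = sqrt(t[type_i, "eps"] * t[type_j, "eps"]))
}

## TRUE where the pair is (donor hydrogen, acceptor) in either order.
is_hbond_pair <- function(type_i, type_j, params) {
  hb_i <- params$types[type_i, "hbond"]
  hb_j <- params$types[type_j, "hbond"]
  (hb_i == "donor" & hb_j == "acceptor") |
    (hb_i == "acceptor" & hb_j == "donor")
}

#' Lennard-Jones 12-6 van der Waals energy (unweighted)
#'
#' @param r Distance(s), Angstrom.
#' @param type_i,type_j AutoDock atom types.
#' @param params [scoring_params()].
#' @return Energy in kcal/mol, before weighting; `-eps_ij` at `r = Rij`,
#'   zero beyond the non-bonded cutoff, capped at `params$max_energy`.
#' @export
vdw_energy <- function(r, type_i, type_j, params = scoring_params()) {
  pe <- pair_rij_eps(type_i, type_j, params)
  rs <- smooth_r(r, rep_len(pe$rij, length(r)), params$smoothing_width)
  A <- pe$eps * pe$rij^12
  B <- 2 * pe$eps * pe$rij^6
  e <- A / rs^12 - B / rs^6
  e <- pmin(e, params$max_energy)
  e[r > params$nb_cutoff] <- 0
  e
}

#' 12-10 hydrogen-bond energy (unweighted, distance-only)
#'
#' Applies to (HD, acceptor) pairs; the well has depth `eps_hb` at
#' `Rij_hb` (1.9 Angstrom / 5.0 kcal/mol for O and N acceptors, 2.5 / 1.0
#' for S). The grid-based angular attenuation of AutoGrid is deliberately
#' not reproduced: for rescoring a fixed pose its effect is constant
#' between wild type and mutant except at the mutated residue.
#'
#' @inheritParams vdw_energy
#' @return Energy in kcal/mol before weighting; 0 for non-H-bonding pairs.
#' @export
hbond_energy <- function(r, type_i, type_j, params = scoring_params()) {
  t <- params$types
  hb <- is_hbond_pair(type_i, type_j, params)
  acc <- ifelse(t[type_i, "hbond"] == "acceptor", type_i, type_j)
  rij <- t[acc, "Rij_hb"]
  eps <- t[acc, "eps_hb"]
  rs <- smooth_r(r, rep_len(rij, length(r)), params$smoothing_width)
  C <- 5 * eps * rij^12
  D <- 6 * eps * rij^10
  e <- C / rs^12 - D / rs^10
  e <- pmin(e, params$max_energy)
  e[!hb] <- 0
  e[r > params$nb_cutoff] <- 0
  e
}

#' Mehler-Solmajer sigmoidal distance-dependent dielectric
#'
#' eps(r) = A + B / (1 + k exp(-lambda B r)) with A = -8.5525, B = eps0 - A,
#' eps0 = 78.4, k = 7.7839, lambda = 0.003627: approaches the bulk-water
#' dielectric at long range and a low effective dielectric at contact.
#'
#' @param r Distance(s), Angstrom.
#' @param params [scoring_params()].
#' @return The dimensionless dielectric.
#' @export
ms_dielectric <- function(r, params = scoring_params()) {
  B <- params$ms_eps0 - params$ms_A
  params$ms_A + B / (1 + params$ms_k * exp(-params$ms_lambda * B * r))
}

#' Screened Coulomb electrostatic energy (unweighted)
#'
#' @param r Distance(s), Angstrom.
#' @param q_i,q_j Partial charges, elementary charge units.
#' @param params [scoring_params()].
#' @return Energy in kcal/mol before weighting; zero beyond the cutoff.
#' @export
elec_energy <- function(r, q_i, q_j, params = scoring_params()) {
  e <- params$coulomb * q_i * q_j / (ms_dielectric(r, params) * r)
  e[r > params$nb_cutoff] <- 0
  e
}

#' Gaussian desolvation energy (unweighted)
#'
#' @param r Distance(s), Angstrom.
#' @param type_i,type_j AutoDock atom types.
#' @param q_i,q_j Partial charges (enter through the charge-dependent
#'   solvation parameter S = solpar + 0.01097 |q|).
#' @param params [scoring_params()].
#' @return Energy in kcal/mol before weighting; zero beyond the cutoff.
#' @export
desolv_energy <- function(r, type_i, type_j, q_i, q_j,
                          params = scoring_params()) {
  t <- params$types
  S_i <- t[type_i, "solpar"] + params$qsolpar * abs(q_i)
  S_j <- t[type_j, "solpar"] + params$qsolpar * abs(q_j)
  V_i <- t[type_i, "vol"]
  V_j <- t[type_j, "vol"]
  e <- (S_i * V_j + S_j * V_i) * exp(-r^2 / (2 * params$desolv_sigma^2))
  e[r > params$nb_cutoff] <- 0
  e
}

#' Intermolecular interaction energy with per-term breakdown
#'
#' Sums the four weighted terms over every (receptor atom, ligand atom)
#' pair within the non-bonded cutoff. The pose is scored as-is; no docking
#' or optimisation is performed.
#'
#' @param receptor A prepared `abscan_structure` (types and charges set).
#' @param ligand An `abscan_ligand` (types and charges set).
#' @param params [scoring_params()].
#' @return An `abscan_energy` list: `vdw`, `hbond`, `elec`, `desolv`
#'   (post-weighting, kcal/mol) and `total` (their exact sum).
#' @export
interaction_energy <- function(receptor, ligand, params = scoring_params()) {
  ra <- receptor$atom
  la <- ligand$atom
  check_scoreable(ra, "receptor")
  check_scoreable(la, "ligand")
  if (nrow(la) == 0 || nrow(ra) == 0) return(energy_breakdown(0, 0, 0, 0))
  p <- neighbor_pairs(coords(ra), params$nb_cutoff, coords(la))
  if (nrow(p) == 0) return(energy_breakdown(0, 0, 0, 0))
  ti <- ra$ad_type[p$i]; tj <- la$ad_type[p$j]
  qi <- ra$charge[p$i]; qj <- la$charge[p$j]
  hb <- is_hbond_pair(ti, tj, params)
  vdw_raw <- sum(ifelse(hb, 0, vdw_energy(p$d, ti, tj, params)))
  hb_raw <- sum(hbond_energy(p$d, ti, tj, params))
  elec_raw <- sum(elec_energy(p$d, qi, qj, params))
  sol_raw <- sum(desolv_energy(p$d, ti, tj, qi, qj, params))
  energy_breakdown(params$W_vdw * vdw_raw, params$W_hb * hb_raw,
                   params$W_elec * elec_raw, params$W_sol * sol_raw)
}

energy_breakdown <- function(vdw, hbond, elec, desolv) {
  structure(list(vdw = vdw, hbond = hbond, elec = elec, desolv = desolv,
                 total = vdw + hbond + elec + desolv),
            class = "abscan_energy")
}

#' @export
print.abscan_energy <- function(x, ...) {
  cat(sprintf("total %8.3f = vdw %8.3f + hbond %8.3f + elec %8.3f + desolv %8.3f kcal/mol\n",
              x$total, x$vdw, x$hbond, x$elec, x$desolv))
  invisible(x)
}

check_scoreable <- function(a, what) {
  bad <- is.na(a$ad_type) | !is.finite(a$charge)
  if (any(bad))
    stop(what, " atom without type/charge: serial ",
         paste(utils::head(a$serial[bad], 3), collapse = ", "),
         " (run preparation first)")
  unknown <- setdiff(unique(a$ad_type), rownames(ad4_type_params()))
  if (length(unknown) > 0)
    stop(what, " atoms carry unparameterised AD type(s): ",
         paste(unknown, collapse = ", "))
}
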