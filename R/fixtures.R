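## Synthetic protein-ligand complexes with known geometry and energetics.
##
## Residues are built from internal-coordinate templates (standard bond
## lengths and angles, fixed rotamers) on an extended backbone, so every
## downstream stage is testable without fetching structures. The
## conformations are idealised, not folded: these are geometric testbeds,
## not physical models.

## Side-chain internal coordinates: atom placed from (ref3, ref2, ref1)
## with bond length, angle and dihedral (degrees). CB is placed first from
## (C, N, CA) with the standard improper; every entry names atoms already
## placed.
SIDECHAIN_ZMAT <- list(
  ALA = list(),
  GLY = list(),
  SER = list(c("OG", "N", "CA", "CB", 1.417, 110.8, 180)),
  CYS = list(c("SG", "N", "CA", "CB", 1.808, 113.8, 180)),
  THR = list(c("OG1", "N", "CA", "CB", 1.433, 109.6, 180),
             c("CG2", "N", "CA", "CB", 1.521, 110.5, 60)),
  VAL = list(c("CG1", "N", "CA", "CB", 1.527, 110.5, 180),
             c("CG2", "N", "CA", "CB", 1.527, 110.5, 60)),
  LEU = list(c("CG", "N", "CA", "CB", 1.530, 116.3, 180),
             c("CD1", "CA", "CB", "CG", 1.521, 110.7, 180),
             c("CD2", "CA", "CB", "CG", 1.521, 110.7, 60)),
  ILE = list(c("CG1", "N", "CA", "CB", 1.530, 110.4, 180),
             c("CG2", "N", "CA", "CB", 1.521, 110.5, 300),
             c("CD1", "CA", "CB", "CG1", 1.513, 113.8, 180)),
  MET = list(c("CG", "N", "CA", "CB", 1.530, 114.1, 180),
             c("SD", "CA", "CB", "CG", 1.803, 112.7, 180),
             c("CE", "CB", "CG", "SD", 1.791, 100.9, 180)),
  PRO = list(c("CG", "N", "CA", "CB", 1.492, 104.5, 30),
             c("CD", "CA", "CB", "CG", 1.503, 106.1, 325)),
  ASP = list(c("CG", "N", "CA", "CB", 1.516, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.249, 118.4, 0),
             c("OD2", "CA", "CB", "CG", 1.249, 118.4, 180)),
  ASN = list(c("CG", "N", "CA", "CB", 1.516, 112.6, 180),
             c("OD1", "CA", "CB", "CG", 1.231, 120.8, 0),
             c("ND2", "CA", "CB", "CG", 1.328, 116.4, 180)),
  GLU = list(c("CG", "N", "CA", "CB", 1.530, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.249, 118.4, 0),
             c("OE2", "CB", "CG", "CD", 1.249, 118.4, 180)),
  GLN = list(c("CG", "N", "CA", "CB", 1.530, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.516, 112.6, 180),
             c("OE1", "CB", "CG", "CD", 1.231, 120.8, 0),
             c("NE2", "CB", "CG", "CD", 1.328, 116.4, 180)),
  LYS = list(c("CG", "N", "CA", "CB", 1.530, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.530, 111.3, 180),
             c("CE", "CB", "CG", "CD", 1.530, 111.3, 180),
             c("NZ", "CG", "CD", "CE", 1.489, 111.9, 180)),
  ARG = list(c("CG", "N", "CA", "CB", 1.530, 114.1, 180),
             c("CD", "CA", "CB", "CG", 1.530, 111.3, 180),
             c("NE", "CB", "CG", "CD", 1.461, 112.0, 180),
             c("CZ", "CG", "CD", "NE", 1.329, 124.2, 180),
             c("NH1", "CD", "NE", "CZ", 1.326, 120.0, 0),
             c("NH2", "CD", "NE", "CZ", 1.326, 120.0, 180)),
  PHE = list(c("CG", "N", "CA", "CB", 1.502, 113.8, 180),
             c("CD1", "CA", "CB", "CG", 1.384, 120.8, 90),
             c("CD2", "CA", "CB", "CG", 1.384, 120.8, 270),
             c("CE1", "CB", "CG", "CD1", 1.382, 120.8, 180),
             c("CE2", "CB", "CG", "CD2", 1.382, 120.8, 180),
             c("CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0)),
  TYR = list(c("CG", "N", "CA", "CB", 1.502, 113.8, 180),
             c("CD1", "CA", "CB", "CG", 1.384, 120.8, 90),
             c("CD2", "CA", "CB", "CG", 1.384, 120.8, 270),
             c("CE1", "CB", "CG", "CD1", 1.382, 120.8, 180),
             c("CE2", "CB", "CG", "CD2", 1.382, 120.8, 180),
             c("CZ", "CG", "CD1", "CE1", 1.382, 120.0, 0),
             c("OH", "CD1", "CE1", "CZ", 1.376, 119.9, 180)),
  TRP = list(c("CG", "N", "CA", "CB", 1.498, 113.6, 180),
             c("CD1", "CA", "CB", "CG", 1.365, 126.9, 90),
             c("CD2", "CA", "CB", "CG", 1.433, 126.7, 270),
             c("NE1", "CB", "CG", "CD1", 1.374, 110.1, 180),
             c("CE2", "CB", "CG", "CD2", 1.409, 107.3, 180),
             c("CE3", "CB", "CG", "CD2", 1.398, 133.9, 0),
             c("CZ2", "CD1", "NE1", "CE2", 1.394, 130.4, 180),
             c("CZ3", "CG", "CD2", "CE3", 1.382, 118.8, 180),
             c("CH2", "NE1", "CE2", "CZ2", 1.368, 117.5, 180)),
  HIS = list(c("CG", "N", "CA", "CB", 1.497, 113.8, 180),
             c("ND1", "CA", "CB", "CG", 1.371, 122.7, 90),
             c("CD2", "CA", "CB", "CG", 1.356, 131.0, 270),
             c("CE1", "CB", "CG", "ND1", 1.319, 109.3, 180),
             c("NE2", "CB", "CG", "CD2", 1.374, 107.2, 180))
)

ELEMENT_OF_NAME <- function(name) guess_element(name)

#' Specify a synthetic protein-ligand complex
#'
#' @param n_residues Chain length.
#' @param residue_names Character vector recycled over the chain (default
#'   `"LEU"`).
#' @param contact_residues Integer indices of residues the ligand must touch
#'   (within 4.5 Angstrom); all others stay outside.
#' @param ligand_atoms Optional data.frame with columns `elem`, `charge` and
#'   (if `contact_residues` is empty) `x`, `y`, `z`. By default one neutral
#'   carbon per contact residue.
#' @param seed Integer seed; the same spec always expands to the same
#'   structure.
#' @return A `toy_spec` list.
#' @export
toy_spec <- function(n_residues, residue_names = "LEU",
                     contact_residues = integer(0), ligand_atoms = NULL,
                     seed = 1) {
  structure(list(n_residues = as.integer(n_residues),
                 residue_names = toupper(rep_len(residue_names, n_residues)),
                 contact_residues = as.integer(contact_residues),
                 ligand_atoms = ligand_atoms, seed = as.integer(seed)),
            class = "toy_spec")
}

#' Build a synthetic protein-ligand complex
#'
#' Expands a [toy_spec()]: an extended poly-peptide with ideal backbone and
#' side-chain geometry, and a ligand (hetero group `LIG`, chain `X`,
#' residue 900) placed so that exactly the requested contact residues fall
#' within 4.5 Angstrom. Placement is verified with [select_binding_site()];
#' a spec whose contacts cannot be realised geometrically is an error.
#'
#' @param spec A [toy_spec()].
#' @return An `abscan_structure`.
#' @export
make_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  set.seed(spec$seed)
  chain <- build_chain(spec$n_residues, spec$residue_names)
  lig <- place_ligand(chain, spec)
  atom <- rbind(chain, lig)
  atom$serial <- seq_len(nrow(atom))
  s <- new_structure(atom, title = "synthetic complex")
  if (length(spec$contact_residues) > 0 || !is.null(spec$ligand_atoms)) {
    sel <- ligand_selector("LIG", "X", 900)
    got <- select_binding_site_quiet(s, sel, 4.5)
    want <- sort(res_id("A", spec$contact_residues))
    if (!identical(sort(got), want))
      stop("impossible placement: requested contacts {",
           paste(spec$contact_residues, collapse = ", "),
           "} but realised site {", paste(got, collapse = ", "), "}")
  }
  s
}

select_binding_site_quiet <- function(s, sel, cutoff) {
  site <- suppressWarnings(select_binding_site(s, sel, cutoff))
  site$residues$res_id
}

## Helical chain (alpha-helix backbone dihedrals keep fixed-rotamer side
## chains clash-free); heavy atoms only, hydrogens come from check_hydrogens.
build_chain <- function(n, resnames, phi = -57, psi = -47, omega = 180) {
  rows <- list()
  prev <- NULL    # list(N, CA, C)
  serial <- 0L
  for (i in seq_len(n)) {
    rn <- resnames[i]
    if (is.null(prev)) {
      N <- c(0, 0, 0)
      CA <- c(1.458, 0, 0)
      C <- nerf_place(c(-1, 1, 0), N, CA, 1.525, 111.2, 0)
    } else {
      N <- nerf_place(prev$N, prev$CA, prev$C, 1.329, 116.2, psi)
      CA <- nerf_place(prev$CA, prev$C, N, 1.458, 121.7, omega)
      C <- nerf_place(prev$C, N, CA, 1.525, 111.2, phi)
    }
    O <- nerf_place(N, CA, C, 1.231, 120.5, psi + 180)
    pos <- list(N = N, CA = CA, C = C, O = O)
    if (!(rn %in% c("GLY"))) {
      pos$CB <- nerf_place(C, N, CA, 1.53, 110.5, 122.5)
      for (z in SIDECHAIN_ZMAT[[rn]]) {
        nm <- z[1]
        pos[[nm]] <- nerf_place(pos[[z[2]]], pos[[z[3]]], pos[[z[4]]],
                                as.numeric(z[5]), as.numeric(z[6]),
                                as.numeric(z[7]))
      }
    }
    for (nm in names(pos)) {
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = nm, alt = "", resname = rn, chain = "A",
        resseq = i, icode = "", x = pos[[nm]][1], y = pos[[nm]][2],
        z = pos[[nm]][3], occ = 1, elem = guess_element(nm), hetero = FALSE,
        ad_type = NA_character_, charge = NA_real_, stringsAsFactors = FALSE)
    }
    prev <- list(N = N, CA = CA, C = C)
  }
  do.call(rbind, rows)
}

## Ligand placement: one atom per contact residue, pushed outward from the
## chain past the residue's side-chain tip; several candidate directions are
## tried and the first whose realised binding site matches is kept.
place_ligand <- function(chain, spec) {
  la <- spec$ligand_atoms
  contacts <- spec$contact_residues
  mk_row <- function(idx, elem, charge, xyz) {
    data.frame(serial = 0L, name = paste0(toupper(elem), idx), alt = "",
               resname = "LIG", chain = "X", resseq = 900L, icode = "",
               x = xyz[1], y = xyz[2], z = xyz[3], occ = 1,
               elem = toupper(elem), hetero = TRUE, ad_type = NA_character_,
               charge = charge, stringsAsFactors = FALSE)
  }
  if (length(contacts) == 0) {
    if (is.null(la)) return(chain[0, ])
    rows <- lapply(seq_len(nrow(la)), function(k)
      mk_row(k, la$elem[k], if (is.null(la$charge)) 0 else la$charge[k],
             c(la$x[k], la$y[k], la$z[k])))
    return(do.call(rbind, rows))
  }
  elems <- if (!is.null(la)) rep_len(la$elem, length(contacts))
           else rep("C", length(contacts))
  charges <- if (!is.null(la) && !is.null(la$charge))
    rep_len(la$charge, length(contacts)) else rep(0, length(contacts))
  ctr <- colMeans(as.matrix(chain[chain$name == "CA", c("x", "y", "z")]))
  rows <- list()
  for (k in seq_along(contacts)) {
    idx <- contacts[k]
    res <- chain[chain$resseq == idx, , drop = FALSE]
    if (nrow(res) == 0) stop("contact residue ", idx, " outside the chain")
    ca <- as.numeric(res[res$name == "CA", c("x", "y", "z")])
    sc <- res[!(res$name %in% c("N", "CA", "C", "O")), , drop = FALSE]
    tip <- if (nrow(sc) > 0) {
      d <- (sc$x - ca[1])^2 + (sc$y - ca[2])^2 + (sc$z - ca[3])^2
      as.numeric(sc[which.max(d), c("x", "y", "z")])
    } else ca
    dirs <- list(unit(tip - ca + 1e-9), unit(tip - ctr), c(0, 0, 1),
                 c(0, 0, -1), c(0, 1, 0), c(0, -1, 0))
    placed <- FALSE
    for (u in dirs) {
      cand <- tip + 3.5 * u
      other <- chain[!(chain$resseq %in% contacts), , drop = FALSE]
      dmin_other <- if (nrow(other) > 0)
        sqrt(min((other$x - cand[1])^2 + (other$y - cand[2])^2 +
                   (other$z - cand[3])^2)) else Inf
      if (dmin_other > 4.6) {
        rows[[k]] <- mk_row(k, elems[k], charges[k], cand)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("impossible placement: cannot put a ligand atom near residue ",
           idx, " without touching other residues")
  }
  do.call(rbind, rows)
}

#' Minimal two-atom scoring fixture
#'
#' One receptor atom and one ligand atom at separation `r` with the given
#' AutoDock types and charges: the smallest testbed on which every scoring
#' term has a closed form.
#'
#' @param type_i Receptor atom AD type.
#' @param type_j Ligand atom AD type.
#' @param r Separation, Angstrom.
#' @param q_i,q_j Partial charges.
#' @return A list with `receptor` (an `abscan_structure`) and `ligand` (an
#'   `abscan_ligand`).
#' @export
make_pair_fixture <- function(type_i, type_j, r, q_i = 0, q_j = 0) {
  t <- ad4_type_params()
  stopifnot(type_i %in% rownames(t), type_j %in% rownames(t))
  elem_of <- function(ty) ad_to_element(ty, ty)
  rec_atom <- data.frame(
    serial = 1L, name = "X1", alt = "", resname = "GLY", chain = "A",
    resseq = 1L, icode = "", x = 0, y = 0, z = 0, occ = 1,
    elem = elem_of(type_i), hetero = FALSE, ad_type = type_i, charge = q_i,
    stringsAsFactors = FALSE)
  lig_atom <- data.frame(
    serial = 2L, name = "Y1", alt = "", resname = "LIG", chain = "X",
    resseq = 900L, icode = "", x = r, y = 0, z = 0, occ = 1,
    elem = elem_of(type_j), hetero = TRUE, ad_type = type_j, charge = q_j,
    stringsAsFactors = FALSE)
  list(
    receptor = new_structure(rec_atom, title = "pair fixture"),
    ligand = structure(list(atom = lig_atom,
                            selector = ligand_selector("LIG", "X", 900),
                            includes_bridge_waters = FALSE),
                       class = "abscan_ligand")
  )
}
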