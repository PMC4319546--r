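## Polar-hydrogen completion for standard residues.
##
## Crystal structures usually carry no hydrogens; the force field needs the
## polar ones (they are the hydrogen-bond donors). Nonpolar hydrogens are
## not added: the united-atom convention would merge them away again.

## Which polar hydrogens each standard residue should carry, keyed by the
## heavy parent atom: name(s) of hydrogens, bond length, geometry class.
POLAR_H_SPEC <- list(
  SER = list(list(parent = "OG",  h = "HG",  len = 0.96, geom = "sp3_1")),
  THR = list(list(parent = "OG1", h = "HG1", len = 0.96, geom = "sp3_1")),
  TYR = list(list(parent = "OH",  h = "HH",  len = 0.96, geom = "sp2_1")),
  CYS = list(list(parent = "SG",  h = "HG",  len = 1.34, geom = "sp3_1")),
  LYS = list(list(parent = "NZ",  h = c("HZ1", "HZ2", "HZ3"), len = 1.01,
                  geom = "sp3_3")),
  ARG = list(list(parent = "NE",  h = "HE",  len = 1.01, geom = "ring_n"),
             list(parent = "NH1", h = c("HH11", "HH12"), len = 1.01,
                  geom = "sp2_2"),
             list(parent = "NH2", h = c("HH21", "HH22"), len = 1.01,
                  geom = "sp2_2")),
  ASN = list(list(parent = "ND2", h = c("HD21", "HD22"), len = 1.01,
                  geom = "sp2_2")),
  GLN = list(list(parent = "NE2", h = c("HE21", "HE22"), len = 1.01,
                  geom = "sp2_2")),
  TRP = list(list(parent = "NE1", h = "HE1", len = 1.01, geom = "ring_n")),
  HIS = list(list(parent = "NE2", h = "HE2", len = 1.01, geom = "ring_n"))
)

#' Complete missing polar hydrogens
#'
#' Adds, at ideal geometry, the polar hydrogens a standard residue should
#' carry but does not: the backbone amide H (three on an N-terminal amine),
#' and the side-chain O-H/N-H/S-H hydrogens (His is protonated on NE2, the
#' common neutral tautomer; Cys in a disulfide gets none). Existing
#' hydrogens are never duplicated, so the operation is idempotent.
#'
#' @param structure An `abscan_structure`.
#' @param bonds Optional pre-computed bond graph (re-inferred otherwise).
#' @return The structure with added hydrogens appended to their residues.
#' @export
check_hydrogens <- function(structure, bonds = infer_bonds(structure)) {
  a <- structure$atom
  uid <- residue_uid(a)
  rec <- !a$hetero
  new_rows <- list()
  nonstd <- unique(a$resname[rec & !(a$resname %in% STANDARD_AA)])
  if (length(nonstd) > 0)
    warning("nonstandard receptor residue(s) left unprotonated: ",
            paste(nonstd, collapse = ", "))
  for (r in unique(uid[rec])) {
    rows <- which(uid == r & rec)
    res <- a[rows, , drop = FALSE]
    if (!(res$resname[1] %in% STANDARD_AA)) next
    new_rows <- c(new_rows,
                  backbone_amide_h(a, rows, bonds),
                  sidechain_polar_h(a, rows, bonds))
  }
  if (length(new_rows) == 0) return(structure)
  add <- do.call(rbind, new_rows)
  add$serial <- max(a$serial) + seq_len(nrow(add))
  out <- rbind(a, add)
  ## keep residues contiguous: order by residue appearance, H after heavy
  first_of <- match(residue_uid(out), unique(residue_uid(out)))
  out <- out[order(first_of, seq_len(nrow(out))), , drop = FALSE]
  new_structure(out, structure$title, structure$source_format)
}

h_row <- function(template, name, xyz) {
  h <- template
  h$name <- name
  h$alt <- ""
  h$x <- xyz[1]; h$y <- xyz[2]; h$z <- xyz[3]
  h$occ <- 1
  h$elem <- "H"
  h$ad_type <- "HD"
  h$charge <- NA_real_
  h
}

atom_xyz <- function(a, row) c(a$x[row], a$y[row], a$z[row])

## Amide H on the backbone nitrogen; N-terminal amine gets H1/H2/H3.
backbone_amide_h <- function(a, rows, bonds) {
  res <- a[rows, , drop = FALSE]
  if (res$resname[1] == "PRO") return(list())
  n_row <- rows[res$name == "N"][1]
  ca_row <- rows[res$name == "CA"][1]
  if (is.na(n_row) || is.na(ca_row)) return(list())
  existing <- a$name[rows]
  nb <- bonds$adj[[n_row]]
  h_on_n <- nb[norm_elem(a$elem[nb]) == "H"]
  if (length(h_on_n) > 0) return(list())
  prev_c <- nb[a$name[nb] == "C" & !(nb %in% rows)]
  out <- list()
  N <- atom_xyz(a, n_row); CA <- atom_xyz(a, ca_row)
  if (length(prev_c) >= 1) {
    if ("H" %in% existing) return(list())
    Cp <- atom_xyz(a, prev_c[1])
    dir <- -(unit(CA - N) + unit(Cp - N))
    xyz <- N + 1.01 * unit(dir)
    out[[1]] <- h_row(a[n_row, , drop = FALSE], "H", xyz)
  } else {
    ## N-terminus: three hydrogens staggered about the N-CA axis
    c_row <- rows[res$name == "C"][1]
    if (is.na(c_row)) return(list())
    Cx <- atom_xyz(a, c_row)
    want <- c("H1", "H2", "H3")
    missing <- setdiff(want, existing)
    for (k in seq_along(want)) {
      if (!want[k] %in% missing) next
      xyz <- nerf_place(Cx, CA, N, 1.01, 109.5, 60 + 120 * (k - 1))
      out[[length(out) + 1L]] <- h_row(a[n_row, , drop = FALSE], want[k], xyz)
    }
  }
  out
}

sidechain_polar_h <- function(a, rows, bonds) {
  res <- a[rows, , drop = FALSE]
  spec <- POLAR_H_SPEC[[res$resname[1]]]
  if (is.null(spec)) return(list())
  out <- list()
  for (s in spec) {
    p_row <- rows[res$name == s$parent][1]
    if (is.na(p_row)) next
    missing <- setdiff(s$h, res$name)
    if (length(missing) == 0) next
    ## disulfide cysteine: SG bonded to another SG gets no H
    nb <- bonds$adj[[p_row]]
    if (s$parent == "SG" && any(a$name[nb] == "SG" & !(nb %in% rows))) next
    if (length(nb[norm_elem(a$elem[nb]) == "H"]) > 0) next
    heavy_nb <- nb[norm_elem(a$elem[nb]) != "H"]
    if (length(heavy_nb) == 0) next
    P <- atom_xyz(a, p_row)
    B <- atom_xyz(a, heavy_nb[1])
    gnb <- setdiff(bonds$adj[[heavy_nb[1]]], p_row)
    gnb <- gnb[norm_elem(a$elem[gnb]) != "H"]
    G <- if (length(gnb) > 0) atom_xyz(a, gnb[1]) else B + c(1, 0, 0)
    place <- switch(s$geom,
      sp3_1 = list(list(ang = 109.5, tor = 180)),
      sp2_1 = list(list(ang = 113, tor = 180)),
      sp2_2 = list(list(ang = 120, tor = 0), list(ang = 120, tor = 180)),
      sp3_3 = list(list(ang = 109.5, tor = 60), list(ang = 109.5, tor = 180),
                   list(ang = 109.5, tor = 300)),
      ring_n = NULL
    )
    if (is.null(place)) {         # ring nitrogen: bisector of the two ring bonds
      if (length(heavy_nb) < 2) next
      B2 <- atom_xyz(a, heavy_nb[2])
      xyz <- P + s$len * unit(-(unit(B - P) + unit(B2 - P)))
      for (hn in missing)
        out[[length(out) + 1L]] <- h_row(a[p_row, , drop = FALSE], hn, xyz)
      next
    }
    for (k in seq_along(s$h)) {
      hn <- s$h[k]
      if (!hn %in% missing) next
      pk <- place[[min(k, length(place))]]
      xyz <- nerf_place(G, B, P, s$len, pk$ang, pk$tor)
      out[[length(out) + 1L]] <- h_row(a[p_row, , drop = FALSE], hn, xyz)
    }
  }
  out
}
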