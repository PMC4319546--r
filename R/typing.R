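## AutoDock atom-type assignment.
##
## Types drive both the pairwise energy parameters and the hydrogen-bond
## roles: A = aromatic carbon, C = aliphatic carbon, OA = acceptor oxygen,
## NA = acceptor nitrogen, N = non-acceptor nitrogen, SA/S = sulfur,
## HD = polar (donor) hydrogen, H = nonpolar hydrogen, halogens/P direct.

#' Assign AutoDock atom types
#'
#' Rules: carbons in planar 5/6-membered rings are aromatic (`A`), other
#' carbons `C`; all oxygens are acceptors (`OA`); a nitrogen is an acceptor
#' (`NA`) iff it carries no hydrogen and has at most two heavy neighbours
#' (pyridine/imidazole-like lone pair), otherwise `N`; sulfur is an acceptor
#' (`SA`) unless bonded to three or more heavy atoms (oxidised, `S`);
#' hydrogens bonded to N/O/S are polar (`HD`), others `H`; F/Cl/Br/I/P map
#' directly.
#'
#' @param structure An `abscan_structure`.
#' @param bonds The [infer_bonds()] graph of the same atoms.
#' @return The structure with the `ad_type` column filled. Atoms of an
#'   element outside the parameter table keep their element symbol as type,
#'   with a warning; scoring will then fail loudly rather than silently.
#' @export
assign_autodock_types <- function(structure, bonds = infer_bonds(structure)) {
  a <- structure$atom
  elem <- norm_elem(a$elem)
  n <- nrow(a)
  deg_heavy <- bond_degree(bonds, elem = a$elem, heavy_only = TRUE)
  has_h <- has_bonded_element(bonds, elem, "H")
  aromatic <- aromatic_carbons(a, bonds, elem)
  ty <- character(n)
  for (i in seq_len(n)) {
    ty[i] <- switch(elem[i],
      C = if (aromatic[i]) "A" else "C",
      O = "OA",
      N = if (!has_h[i] && deg_heavy[i] <= 2) "NA" else "N",
      S = if (deg_heavy[i] >= 3) "S" else "SA",
      H = {
        nb <- bonds$adj[[i]]
        if (length(nb) > 0 && any(elem[nb] %in% c("N", "O", "S"))) "HD" else "H"
      },
      F = "F", CL = "Cl", BR = "Br", I = "I", P = "P",
      NA_character_
    )
    if (is.na(ty[i])) ty[i] <- elem[i]
  }
  unknown <- setdiff(unique(ty), rownames(ad4_type_params()))
  if (length(unknown) > 0)
    warning("element(s) without force-field parameters typed as-is: ",
            paste(unknown, collapse = ", "))
  structure$atom$ad_type <- ty
  structure
}

## TRUE for atoms bonded to at least one atom of `what`.
has_bonded_element <- function(bonds, elem, what) {
  out <- logical(bonds$n)
  e <- bonds$edges
  if (nrow(e) == 0) return(out)
  m1 <- elem[e[, 2]] == what
  m2 <- elem[e[, 1]] == what
  out[e[m1, 1]] <- TRUE
  out[e[m2, 2]] <- TRUE
  out
}

## Carbons that belong to a planar 5- or 6-membered ring.
aromatic_carbons <- function(atom, bonds, elem = norm_elem(atom$elem)) {
  out <- logical(nrow(atom))
  rings <- find_small_rings(atom, bonds, elem)
  xyz <- coords(atom)
  for (ring in rings) {
    if (ring_planar(xyz[ring, , drop = FALSE])) {
      cs <- ring[elem[ring] == "C"]
      out[cs] <- TRUE
    }
  }
  out
}

## 5- and 6-membered rings of C/N/O/S atoms, via shortest alternative path
## per edge on the bond graph (an SSSR-style enumeration adequate for amino
## acids and drug-like ligands).
find_small_rings <- function(atom, bonds, elem = norm_elem(atom$elem)) {
  e <- bonds$edges
  if (nrow(e) == 0) return(list())
  cand_atom <- elem %in% c("C", "N", "O", "S") &
    bond_degree(bonds, elem = atom$elem, heavy_only = TRUE) >= 2
  cand_edge <- cand_atom[e[, 1]] & cand_atom[e[, 2]]
  if (!any(cand_edge)) return(list())
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  if (igraph::vcount(g) < bonds$n)
    g <- igraph::add_vertices(g, bonds$n - igraph::vcount(g))
  rings <- list()
  seen <- character(0)
  for (k in which(cand_edge)) {
    i <- e[k, 1]; j <- e[k, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = i, to = j, output = "vpath"))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) %in% c(5, 6)) {
      key <- paste(sort(path), collapse = "-")
      if (!key %in% seen) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- path
      }
    }
  }
  rings
}

## Mean out-of-plane deviation below 0.1 Angstrom counts as planar.
ring_planar <- function(xyz, tol = 0.1) {
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  normal <- sv$v[, 3]
  mean(abs(sweep(xyz, 2, ctr) %*% normal)) < tol
}
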