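## Distance-based bond perception.

#' Infer covalent bonds from interatomic distances
#'
#' Two atoms are bonded iff their distance is below the sum of their covalent
#' radii plus a 0.45 Angstrom tolerance. A hydrogen keeps at most one bond:
#' its nearest heavy atom.
#'
#' @param structure An `abscan_structure` (or a bare atom table).
#' @return An object of class `abscan_bonds`: `edges` (two-column integer
#'   matrix of atom row indices, i < j), `adj` (adjacency list), `n` atoms.
#' @export
infer_bonds <- function(structure) {
  a <- if (is.data.frame(structure)) structure else structure$atom
  n <- nrow(a)
  radii <- covalent_radii[norm_elem(a$elem)]
  radii[is.na(radii)] <- 1.3   # generous default for exotic elements
  maxcut <- 2 * max(radii) + BOND_TOLERANCE
  p <- neighbor_pairs(coords(a), maxcut)
  if (nrow(p) > 0) {
    ## lower bound: a contact far below any covalent length is a clash,
    ## not a bond
    keep <- p$d > 0.4 * (radii[p$i] + radii[p$j]) &
      p$d < (radii[p$i] + radii[p$j] + BOND_TOLERANCE)
    p <- p[keep, , drop = FALSE]
  }
  ## hydrogens: keep only the bond to the nearest heavy atom
  is_h <- norm_elem(a$elem) == "H"
  if (any(is_h) && nrow(p) > 0) {
    hh <- is_h[p$i] & is_h[p$j]
    p <- p[!hh, , drop = FALSE]
    h_of_pair <- ifelse(is_h[p$i], p$i, ifelse(is_h[p$j], p$j, NA_integer_))
    involved <- !is.na(h_of_pair)
    if (any(involved)) {
      ord <- order(h_of_pair, p$d)
      dup <- duplicated(h_of_pair[ord]) & !is.na(h_of_pair[ord])
      drop_rows <- ord[dup]
      if (length(drop_rows) > 0) p <- p[-drop_rows, , drop = FALSE]
    }
  }
  edges <- cbind(i = p$i, j = p$j)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
    adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
  }
  with_class(list(edges = edges, adj = adj, n = n, tol = BOND_TOLERANCE),
             "abscan_bonds")
}

#' @export
print.abscan_bonds <- function(x, ...) {
  cat(sprintf("<abscan_bonds> %d bonds over %d atoms\n", nrow(x$edges), x$n))
  invisible(x)
}

## Degree vector; optionally counting heavy neighbors only.
bond_degree <- function(bonds, elem = NULL, heavy_only = FALSE) {
  deg <- integer(bonds$n)
  e <- bonds$edges
  if (nrow(e) == 0) return(deg)
  if (heavy_only) {
    is_h <- norm_elem(elem) == "H"
    for (k in seq_len(nrow(e))) {
      i <- e[k, 1]; j <- e[k, 2]
      if (!is_h[j]) deg[i] <- deg[i] + 1L
      if (!is_h[i]) deg[j] <- deg[j] + 1L
    }
  } else {
    t <- tabulate(c(e[, 1], e[, 2]), nbins = bonds$n)
    deg <- as.integer(t)
  }
  deg
}
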