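## Alanine truncation and stereochemical sanity checks.

#' Mutate a residue to alanine
#'
#' Geometric truncation: side-chain atoms beyond C-beta are deleted
#' (including side-chain hydrogens), C-beta is placed at the ideal 1.53
#' Angstrom from C-alpha along the existing CA->CB direction (or rebuilt at
#' ideal tetrahedral geometry if absent), the residue is renamed ALA, and no
#' other atom moves. Alanine removes the side chain without introducing new
#' chemistry, so no rotamer search is needed and the ligand pose is kept
#' fixed.
#'
#' @param structure The complex (an `abscan_structure`).
#' @param residue Residue id string `"CHAIN:RESSEQ[:ICODE]"`.
#' @param ligand Optional `abscan_ligand` whose atoms join the clash check.
#' @return An object of class `abscan_mutant`: `structure`, `mutated`
#'   (residue id), `removed_atoms`, `clash_report`, `skipped` (`FALSE`, or a
#'   reason string when the residue is ALA/GLY/nonstandard, in which case
#'   the structure is returned unchanged).
#' @export
mutate_to_alanine <- function(structure, residue, ligand = NULL) {
  a <- structure$atom
  mask <- residue_mask(a, residue) & !a$hetero
  if (!any(mask)) stop("residue ", residue, " not found in receptor")
  resname <- a$resname[mask][1]
  skip_reason <- NULL
  if (resname == "ALA") skip_reason <- "already alanine"
  if (resname == "GLY") skip_reason <- "glycine (mutation would add atoms)"
  if (!(resname %in% STANDARD_AA) && is.null(skip_reason))
    skip_reason <- paste0("nonstandard residue ", resname)
  if (!is.null(skip_reason)) {
    return(with_class(list(structure = structure, mutated = residue,
                           removed_atoms = character(0), clash_report = NULL,
                           skipped = skip_reason), "abscan_mutant"))
  }
  if (resname == "PRO")
    warning("mutating PRO ", residue, " opens the pyrrolidine ring")
  rows <- which(mask)
  keep_names <- ALA_ATOMS
  is_sidechain_h <- grepl("^[0-9]*H[BGDEZH]", a$name[rows]) &
    !(a$name[rows] %in% keep_names)
  remove <- rows[!(a$name[rows] %in% keep_names) | is_sidechain_h]
  removed_atoms <- a$name[remove]
  a$resname[mask] <- "ALA"
  ca <- rows[a$name[rows] == "CA"][1]
  cb <- rows[a$name[rows] == "CB"][1]
  if (!is.na(cb) && !is.na(ca)) {
    CA <- atom_xyz(a, ca)
    dir <- unit(atom_xyz(a, cb) - CA)
    new_cb <- CA + 1.53 * dir
    a$x[cb] <- new_cb[1]; a$y[cb] <- new_cb[2]; a$z[cb] <- new_cb[3]
  } else if (is.na(cb) && !is.na(ca)) {
    n_row <- rows[a$name[rows] == "N"][1]
    c_row <- rows[a$name[rows] == "C"][1]
    if (!is.na(n_row) && !is.na(c_row)) {
      xyz <- nerf_place(atom_xyz(a, c_row), atom_xyz(a, n_row),
                        atom_xyz(a, ca), 1.53, 110.5, 122.5)
      cb_row <- a[ca, , drop = FALSE]
      cb_row$name <- "CB"; cb_row$elem <- "C"; cb_row$resname <- "ALA"
      cb_row$x <- xyz[1]; cb_row$y <- xyz[2]; cb_row$z <- xyz[3]
      cb_row$ad_type <- if (!is.na(cb_row$ad_type)) "C" else NA_character_
      cb_row$charge <- if (is.finite(cb_row$charge)) 0 else NA_real_
      cb_row$serial <- max(a$serial) + 1L
      a <- rbind(a, cb_row)
    }
  }
  if (length(remove) > 0) a <- a[-remove, , drop = FALSE]
  mut <- new_structure(a, structure$title, structure$source_format)
  rep <- clash_report(mut, ligand = ligand)
  with_class(list(structure = mut, mutated = residue,
                  removed_atoms = removed_atoms, clash_report = rep,
                  skipped = FALSE), "abscan_mutant")
}

#' @export
print.abscan_mutant <- function(x, ...) {
  if (!isFALSE(x$skipped)) {
    cat("<abscan_mutant>", x$mutated, "skipped:", x$skipped, "\n")
  } else {
    cat(sprintf("<abscan_mutant> %s -> ALA (%d atoms removed, %d clash(es))\n",
                x$mutated, length(x$removed_atoms),
                x$clash_report$n_clashes))
  }
  invisible(x)
}

#' Steric-clash report
#'
#' A clash is a non-bonded atom pair (not bonded, not sharing a bonded
#' neighbour) closer than 0.6 times the sum of the element vdW radii.
#'
#' @param structure An `abscan_structure`.
#' @param ligand Optional `abscan_ligand` included in the check.
#' @return A list: `n_clashes`, `worst_overlap` (Angstrom below the clash
#'   threshold for the worst pair), and `pairs` (serials + distance).
#' @export
clash_report <- function(structure, ligand = NULL) {
  a <- structure$atom
  if (!is.null(ligand)) {
    la <- ligand$atom
    for (col in setdiff(ATOM_COLS, names(la))) la[[col]] <- NA
    a <- rbind(a[, ATOM_COLS], la[, ATOM_COLS])
  }
  radii <- element_vdw_radii[norm_elem(a$elem)]
  radii[is.na(radii)] <- 1.7
  maxthr <- CLASH_FRACTION * 2 * max(radii)
  p <- neighbor_pairs(coords(a), maxthr)
  if (nrow(p) > 0) {
    thr <- CLASH_FRACTION * (radii[p$i] + radii[p$j])
    p <- p[p$d < thr & p$d > 1e-6, , drop = FALSE]
    if (nrow(p) > 0) {
      ## exclude bonded (1-2) and angle (1-3) pairs
      bonds <- infer_bonds(new_structure(a))
      excl <- onetwo_onethree(bonds)
      key <- paste(pmin(p$i, p$j), pmax(p$i, p$j))
      p <- p[!(key %in% excl), , drop = FALSE]
    }
  }
  if (nrow(p) == 0)
    return(list(n_clashes = 0L, worst_overlap = 0,
                pairs = data.frame(serial_i = integer(0), serial_j = integer(0),
                                   distance = numeric(0))))
  thr <- CLASH_FRACTION * (radii[p$i] + radii[p$j])
  list(
    n_clashes = nrow(p),
    worst_overlap = max(thr - p$d),
    pairs = data.frame(serial_i = a$serial[p$i], serial_j = a$serial[p$j],
                       distance = p$d)
  )
}

## "i j" keys of 1-2 and 1-3 pairs of a bond graph.
onetwo_onethree <- function(bonds) {
  e <- bonds$edges
  keys <- character(0)
  if (nrow(e) > 0)
    keys <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  for (c_idx in seq_len(bonds$n)) {
    nb <- bonds$adj[[c_idx]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      keys <- c(keys, paste(cmb[1, ], cmb[2, ]))
    }
  }
  unique(keys)
}

#' Model quality from the steric-clash metric
#'
#' Reports the clash count and worst overlap of a mutant model and flags it
#' `poor` when any clash survives. (A statistical-potential model score is
#' deliberately not computed; truncation-only mutants need only a broken /
#' not-broken certificate.)
#'
#' @param model An `abscan_mutant`.
#' @return A list: `n_clashes`, `worst_overlap`, `poor`.
#' @export
model_quality <- function(model) {
  if (!isFALSE(model$skipped))
    return(list(n_clashes = NA_integer_, worst_overlap = NA_real_, poor = NA))
  cr <- model$clash_report
  list(n_clashes = cr$n_clashes, worst_overlap = cr$worst_overlap,
       poor = cr$n_clashes > 0)
}

#' Local clash-relief minimisation
#'
#' A soft-sphere relaxation restricted to atoms within 5 Angstrom of the
#' mutated residue: a steepest-descent stage (up to `max_cg_iterations`
#' steps, stopping when the largest per-step atom shift falls below
#' `min_shift`), followed by `md_steps` annealing-style steps with small
#' seeded random kicks of decreasing amplitude. Forces are repulsive-only
#' between non-bonded pairs below their contact distance, plus harmonic
#' bond-length terms and a weak positional tether, so relief never drifts
#' the model far from the crystal coordinates. Atoms beyond 5 Angstrom of
#' the mutated residue are bitwise unchanged. Off by default in the scan:
#' truncation cannot create new contacts, so minimisation is only useful
#' for strained input models.
#'
#' @param model An `abscan_mutant`.
#' @param max_cg_iterations Maximum descent iterations, default 200.
#' @param min_shift Convergence threshold on the largest atom shift,
#'   Angstrom, default 0.001.
#' @param md_steps Annealing steps, default 200.
#' @param seed Integer seed making the annealing stage reproducible.
#' @return The model with relaxed coordinates and an updated clash report;
#'   `minimized = TRUE`, or `diverged = TRUE` if the relaxation blew up (the
#'   unminimised model is then returned).
#' @export
minimize_local <- function(model, max_cg_iterations = 200, min_shift = 0.001,
                           md_steps = 200, seed = 1) {
  if (!isFALSE(model$skipped)) return(model)
  if (model$clash_report$n_clashes == 0) {      # no force: immediate convergence
    model$minimized <- TRUE
    return(model)
  }
  s <- model$structure
  a <- s$atom
  xyz0 <- coords(a)
  mres <- which(residue_mask(a, model$mutated))
  if (length(mres) == 0) return(model)
  d_to_res <- apply(neighbor_dist_matrix(xyz0, xyz0[mres, , drop = FALSE]), 1, min)
  movable <- d_to_res <= 5.0
  radii <- element_vdw_radii[norm_elem(a$elem)]
  radii[is.na(radii)] <- 1.7
  bonds <- infer_bonds(s)
  xyz <- xyz0
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  run_stage <- function(xyz, n_steps, kick) {
    step <- 0.05
    last_shift <- Inf
    grow <- 0L
    for (it in seq_len(n_steps)) {
      f <- soft_sphere_forces(xyz, radii, bonds, xyz0)
      f[!movable, ] <- 0
      if (kick > 0) {
        amp <- kick * (1 - it / n_steps)
        f[movable, ] <- f[movable, ] +
          matrix(stats::rnorm(sum(movable) * 3, sd = amp), ncol = 3)
      }
      shift <- sqrt(rowSums(f^2)) * step
      mx <- max(shift, 0)
      if (mx > 0.2) f <- f * (0.2 / mx / step)   # cap per-step displacement
      xyz <- xyz + f * step
      if (mx < min_shift && kick == 0) break
      if (mx > 10 * last_shift) grow <- grow + 1L else grow <- 0L
      if (grow >= 10) return(structure(xyz, diverged = TRUE))
      last_shift <- max(mx, 1e-12)
    }
    xyz
  }
  xyz <- run_stage(xyz, max_cg_iterations, kick = 0)
  if (isTRUE(attr(xyz, "diverged"))) {
    model$diverged <- TRUE
    return(model)
  }
  xyz <- run_stage(xyz, md_steps, kick = 0.002)
  xyz <- run_stage(xyz, max_cg_iterations, kick = 0)  # settle after kicks
  if (isTRUE(attr(xyz, "diverged"))) {
    model$diverged <- TRUE
    return(model)
  }
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  model$structure$atom <- a
  new_rep <- clash_report(model$structure)
  if (new_rep$n_clashes <= model$clash_report$n_clashes) {
    model$clash_report <- new_rep
    model$minimized <- TRUE
  } else {                     # never accept a worse model
    model$structure$atom$x <- xyz0[, 1]
    model$structure$atom$y <- xyz0[, 2]
    model$structure$atom$z <- xyz0[, 3]
    model$minimized <- FALSE
  }
  model
}

## Dense distance matrix between two coordinate sets (small inputs only).
neighbor_dist_matrix <- function(A, B) {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  dz <- outer(A[, 3], B[, 3], "-")
  sqrt(dx * dx + dy * dy + dz * dz)
}

## Gradient of the soft-sphere + bond + tether pseudo-energy.
soft_sphere_forces <- function(xyz, radii, bonds, xyz0,
                               k_rep = 1, k_bond = 5, k_tether = 0.05) {
  n <- nrow(xyz)
  f <- matrix(0, n, 3)
  contact <- 0.75 * outer(radii, radii, "+")
  p <- neighbor_pairs(xyz, max(contact))
  if (nrow(p) > 0) {
    excl <- onetwo_onethree(bonds)
    key <- paste(pmin(p$i, p$j), pmax(p$i, p$j))
    p <- p[!(key %in% excl), , drop = FALSE]
    thr <- 0.75 * (radii[p$i] + radii[p$j])
    p <- p[p$d < thr & p$d > 1e-6, , drop = FALSE]
    for (k in seq_len(nrow(p))) {
      i <- p$i[k]; j <- p$j[k]
      dvec <- xyz[i, ] - xyz[j, ]
      mag <- k_rep * (0.75 * (radii[i] + radii[j]) - p$d[k])
      dir <- dvec / p$d[k]
      f[i, ] <- f[i, ] + mag * dir
      f[j, ] <- f[j, ] - mag * dir
    }
  }
  e <- bonds$edges
  if (nrow(e) > 0) {
    d0 <- sqrt(rowSums((xyz0[e[, 1], , drop = FALSE] -
                          xyz0[e[, 2], , drop = FALSE])^2))
    d <- sqrt(rowSums((xyz[e[, 1], , drop = FALSE] -
                         xyz[e[, 2], , drop = FALSE])^2))
    for (k in seq_len(nrow(e))) {
      if (d[k] < 1e-6) next
      i <- e[k, 1]; j <- e[k, 2]
      mag <- -k_bond * (d[k] - d0[k])
      dir <- (xyz[i, ] - xyz[j, ]) / d[k]
      f[i, ] <- f[i, ] + mag * dir
      f[j, ] <- f[j, ] - mag * dir
    }
  }
  f - k_tether * (xyz - xyz0)
}
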