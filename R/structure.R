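## Internal structure model: a flat atom table plus light S3 wrappers.

ATOM_COLS <- c("serial", "name", "alt", "resname", "chain", "resseq", "icode",
               "x", "y", "z", "occ", "elem", "hetero", "ad_type", "charge")

## class() setter usable inside functions whose argument shadows base::structure
with_class <- function(x, cls) {
  class(x) <- cls
  x
}

#' Construct a structure from an atom table
#'
#' The atom table is the package's working representation: one row per atom
#' with identity (`serial`, `name`, `alt`), residue assignment (`resname`,
#' `chain`, `resseq`, `icode`), coordinates (`x`, `y`, `z` in Angstrom),
#' `occ`upancy, `elem`ent, a `hetero` flag, and the slots filled during
#' force-field preparation (`ad_type`, `charge`).
#'
#' @param atom data.frame with the columns listed above (missing preparation
#'   columns are added as `NA`).
#' @param title Free-text title.
#' @param source_format `"pdb"`, `"pdbqt"` or `"generated"`.
#' @return An object of class `abscan_structure`.
#' @export
new_structure <- function(atom, title = "", source_format = "generated") {
  if (!is.data.frame(atom)) stop("`atom` must be a data.frame")
  if (is.null(atom$alt)) atom$alt <- ""
  if (is.null(atom$icode)) atom$icode <- ""
  if (is.null(atom$occ)) atom$occ <- 1
  if (is.null(atom$ad_type)) atom$ad_type <- NA_character_
  if (is.null(atom$charge)) atom$charge <- NA_real_
  missing <- setdiff(ATOM_COLS, names(atom))
  if (length(missing) > 0)
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  atom <- atom[, ATOM_COLS]
  rownames(atom) <- NULL
  bad <- !is.finite(atom$x) | !is.finite(atom$y) | !is.finite(atom$z)
  if (any(bad)) stop("non-finite coordinates for atom serial(s): ",
                     paste(atom$serial[bad], collapse = ", "))
  if (anyDuplicated(atom$serial)) {
    atom$serial <- seq_len(nrow(atom))
  }
  structure(list(atom = atom, title = title, source_format = source_format),
            class = "abscan_structure")
}

#' @export
print.abscan_structure <- function(x, ...) {
  a <- x$atom
  cat(sprintf("<abscan_structure> %d atoms, %d residues (%d hetero atoms)\n",
              nrow(a), length(unique(residue_uid(a))), sum(a$hetero)))
  if (nzchar(x$title)) cat("  title:", x$title, "\n")
  invisible(x)
}

## Unique residue key "chain:resseq:icode" for every atom row.
residue_uid <- function(atom) {
  paste(atom$chain, atom$resseq, atom$icode, sep = ":")
}

#' Format a residue identifier
#'
#' Residues are addressed as `"CHAIN:RESSEQ"` (with an insertion code
#' appended as `"CHAIN:RESSEQ:ICODE"` when present).
#'
#' @param chain Chain identifier.
#' @param resseq Residue sequence number.
#' @param icode Insertion code, default empty.
#' @return The identifier string.
#' @export
res_id <- function(chain, resseq, icode = "") {
  n <- length(resseq)
  if (n == 0) return(character(0))
  chain <- rep_len(chain, n)
  icode <- rep_len(icode, n)
  out <- paste(chain, resseq, sep = ":")
  has <- icode != ""
  out[has] <- paste(chain[has], resseq[has], icode[has], sep = ":")
  out
}

## Parse "CHAIN:RESSEQ[:ICODE]" into its parts.
parse_res_id <- function(id) {
  parts <- strsplit(id, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2) stop("bad residue id: ", id,
                              " (expected CHAIN:RESSEQ[:ICODE])")
  list(chain = parts[1], resseq = as.integer(parts[2]),
       icode = if (length(parts) >= 3) parts[3] else "")
}

## Logical row mask for one residue.
residue_mask <- function(atom, id) {
  p <- parse_res_id(id)
  atom$chain == p$chain & atom$resseq == p$resseq & atom$icode == p$icode
}

#' Split a structure into receptor and hetero parts
#'
#' @param structure An `abscan_structure`.
#' @return A list with `receptor` and `hetero` structures (either may have
#'   zero atoms).
#' @export
split_receptor_hetero <- function(structure) {
  a <- structure$atom
  list(
    receptor = new_structure(a[!a$hetero, , drop = FALSE], structure$title,
                             structure$source_format),
    hetero = new_structure(a[a$hetero, , drop = FALSE], structure$title,
                           structure$source_format)
  )
}

## Coordinates as an n x 3 matrix.
coords <- function(x) {
  a <- if (is.data.frame(x)) x else x$atom
  cbind(a$x, a$y, a$z)
}

## Element normalization: uppercase, e.g. "Cl" -> "CL".
norm_elem <- function(e) toupper(trimws(e))

## Element -> default AutoDock type for atoms whose context is unknown.
element_to_ad <- c(C = "C", N = "N", O = "OA", S = "SA", H = "H",
                   F = "F", CL = "Cl", BR = "Br", I = "I", P = "P")

## Infer the element from a PDB atom name when the element columns are blank.
guess_element <- function(name) {
  vapply(name, function(nm) {
    nm <- toupper(gsub("[0-9'\"*]", "", trimws(nm)))
    if (nm == "") return("X")
    two <- substr(nm, 1, 2)
    if (two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "MN", "CU", "NI", "CO"))
      return(two)
    substr(nm, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

## All pairs (i, j), i < j, with distance <= cutoff, between rows of xyz (or
## between xyz and xyz2 when given, with j indexing xyz2).  Plain block-wise
## evaluation: structures here are small enough that this beats maintaining a
## spatial index.
neighbor_pairs <- function(xyz, cutoff, xyz2 = NULL) {
  cross <- !is.null(xyz2)
  if (!cross) xyz2 <- xyz
  n1 <- nrow(xyz); n2 <- nrow(xyz2)
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  if (n1 == 0 || n2 == 0)
    return(data.frame(i = out_i, j = out_j, d = out_d))
  block <- max(1L, floor(4e6 / max(1L, n2)))
  for (s in seq(1L, n1, by = block)) {
    e <- min(n1, s + block - 1L)
    idx <- s:e
    dx <- outer(xyz[idx, 1], xyz2[, 1], "-")
    dy <- outer(xyz[idx, 2], xyz2[, 2], "-")
    dz <- outer(xyz[idx, 3], xyz2[, 3], "-")
    d2 <- dx * dx + dy * dy + dz * dz
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hit) > 0) {
      ii <- idx[hit[, 1]]; jj <- hit[, 2]
      keep <- if (cross) rep(TRUE, length(ii)) else ii < jj
      out_i <- c(out_i, ii[keep])
      out_j <- c(out_j, jj[keep])
      out_d <- c(out_d, sqrt(d2[hit][keep]))
    }
  }
  data.frame(i = out_i, j = out_j, d = out_d)
}
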