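## Ligand selection and binding-site residue detection.

#' Construct a ligand selector
#'
#' @param resname Hetero-group residue name (e.g. `"TES"`).
#' @param chain Chain identifier.
#' @param resseq Residue sequence number.
#' @return An object of class `abscan_selector`.
#' @export
ligand_selector <- function(resname, chain, resseq) {
  structure(list(resname = toupper(trimws(resname)), chain = trimws(chain),
                 resseq = as.integer(resseq)),
            class = "abscan_selector")
}

## Accepts an abscan_selector or "RESNAME:CHAIN:RESSEQ".
as_ligand_selector <- function(x) {
  if (inherits(x, "abscan_selector")) return(x)
  if (is.character(x) && length(x) == 1) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3)
      stop("ligand selector must be RESNAME:CHAIN:RESSEQ (e.g. TES:A:500)")
    return(ligand_selector(parts[1], parts[2], parts[3]))
  }
  stop("cannot interpret ligand selector")
}

format_selector <- function(s) paste(s$resname, s$chain, s$resseq, sep = ":")

#' @export
print.abscan_selector <- function(x, ...) {
  cat("<ligand>", format_selector(x), "\n")
  invisible(x)
}

#' List ligand candidates in a structure
#'
#' All hetero groups except waters (HOH/WAT/DOD) and single-atom ions,
#' ordered by heavy-atom count, largest first.
#'
#' @param structure An `abscan_structure`.
#' @return A list of [ligand_selector()] objects with a `n_heavy` attribute
#'   each.
#' @export
list_ligand_candidates <- function(structure) {
  a <- structure$atom
  het <- a[a$hetero & !(a$resname %in% WATER_NAMES), , drop = FALSE]
  if (nrow(het) == 0) stop("no ligand found: structure has no suitable hetero group")
  uid <- residue_uid(het)
  heavy <- norm_elem(het$elem) != "H"
  counts <- tapply(heavy, uid, sum)
  keep <- names(counts)[counts > 1]      # single-atom ions excluded
  if (length(keep) == 0)
    stop("no ligand found: only waters/ions among hetero groups")
  keep <- keep[order(-counts[keep])]
  lapply(keep, function(u) {
    row <- het[match(u, uid), ]
    sel <- ligand_selector(row$resname, row$chain, row$resseq)
    attr(sel, "n_heavy") <- as.integer(counts[[u]])
    sel
  })
}

#' Select the binding-site residues around a ligand
#'
#' A receptor residue belongs to the binding site iff the minimum over all
#' (residue atom, ligand atom) Euclidean distances is at most `cutoff`.
#' Hydrogens participate on both sides. Waters, ions and hetero residues
#' are never site members; hetero ligand atoms other than the selected
#' ligand do not define the site.
#'
#' @param structure The complex (or a prepared receptor).
#' @param ligand A selector (resolved against the structure's hetero atoms)
#'   or an `abscan_ligand` carrying its own coordinates.
#' @param cutoff Distance cutoff in Angstrom; default 4.5.
#' @return An object of class `abscan_site`: a data.frame `residues` with
#'   `res_id`, `resname`, `min_distance`, `n_contact_atoms`, sorted by
#'   residue id, plus the `cutoff` used.
#' @export
select_binding_site <- function(structure, ligand, cutoff = 4.5) {
  stopifnot(cutoff > 0)
  lig_xyz <- ligand_coords(structure, ligand)
  a <- structure$atom
  rec <- which(!a$hetero)
  res <- data.frame(res_id = character(0), resname = character(0),
                    min_distance = numeric(0), n_contact_atoms = integer(0),
                    stringsAsFactors = FALSE)
  if (length(rec) > 0 && nrow(lig_xyz) > 0) {
    p <- neighbor_pairs(coords(a)[rec, , drop = FALSE], cutoff, lig_xyz)
    if (nrow(p) > 0) {
      rows <- rec[p$i]
      uid <- residue_uid(a)[rows]
      mind <- tapply(p$d, uid, min)
      ncontact <- tapply(rows, uid, function(r) length(unique(r)))
      first <- match(names(mind), uid)
      ids <- res_id(a$chain[rows[first]], a$resseq[rows[first]],
                    a$icode[rows[first]])
      res <- data.frame(res_id = ids,
                        resname = a$resname[rows[first]],
                        min_distance = as.numeric(mind),
                        n_contact_atoms = as.integer(ncontact),
                        stringsAsFactors = FALSE)
      res <- res[order(res$res_id), , drop = FALSE]
      rownames(res) <- NULL
    }
  }
  if (nrow(res) == 0)
    warning("empty binding site at cutoff ", cutoff, " Angstrom")
  with_class(list(residues = res, cutoff = cutoff), "abscan_site")
}

#' @export
print.abscan_site <- function(x, ...) {
  cat(sprintf("<abscan_site> %d residue(s) within %.2f A\n",
              nrow(x$residues), x$cutoff))
  if (nrow(x$residues) > 0) print(x$residues, ...)
  invisible(x)
}

## Ligand coordinates for site detection: from an abscan_ligand directly, or
## by resolving a selector against the structure's hetero atoms.
ligand_coords <- function(structure, ligand) {
  if (inherits(ligand, "abscan_ligand")) return(coords(ligand$atom))
  sel <- as_ligand_selector(ligand)
  a <- structure$atom
  mask <- a$hetero & a$resname == sel$resname & a$chain == sel$chain &
    a$resseq == sel$resseq
  if (!any(mask)) stop("ligand ", format_selector(sel), " not found")
  coords(a[mask, , drop = FALSE])
}
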