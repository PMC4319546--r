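## Receptor and ligand preparation pipelines.

#' Prepare a receptor for scoring
#'
#' Mirrors the AutoDock receptor-preparation contract: complete missing
#' polar hydrogens (`check_hydrogens` behaviour), assign AutoDock atom
#' types, compute Gasteiger PEOE charges with ionised side chains and
#' termini, then merge any nonpolar hydrogens into their parent carbons
#' (united-atom convention).
#'
#' @param structure An `abscan_structure`; only its non-hetero atoms are
#'   used.
#' @return The prepared receptor: polar-hydrogen-only, typed, charged.
#' @export
prepare_receptor <- function(structure) {
  rec <- split_receptor_hetero(structure)$receptor
  if (nrow(rec$atom) == 0) stop("structure has no receptor (ATOM) records")
  bonds <- infer_bonds(rec)
  rec <- assign_autodock_types(rec, bonds)
  rec <- check_hydrogens(rec, bonds)
  bonds <- infer_bonds(rec)
  rec <- assign_autodock_types(rec, bonds)
  rec <- assign_gasteiger_charges(rec, bonds)
  rec <- unite_nonpolar_hydrogens(rec, bonds = bonds_subset_ok(rec, bonds))
  rec
}

## The bond graph indexes atom rows; after operations that only append or
## delete rows we re-infer rather than remap. Small structures make this
## cheap; correctness beats cleverness here.
bonds_subset_ok <- function(structure, bonds) {
  if (bonds$n == nrow(structure$atom)) bonds else infer_bonds(structure)
}

#' Prepare a ligand from the complex itself
#'
#' Types and charges the selected hetero group natively: bonds are inferred
#' from the geometry, AutoDock types assigned, and Gasteiger charges
#' computed with a neutral formal-charge seed. For ligands with metals,
#' unusual atom types, non-zero formal charge or bridge waters, supply a
#' prepared PDBQT via [read_pdbqt()] instead.
#'
#' @param structure The complex.
#' @param selector A ligand selector (see [ligand_selector()]) or a
#'   `"RESNAME:CHAIN:RESSEQ"` string.
#' @return An `abscan_ligand`.
#' @export
prepare_ligand <- function(structure, selector) {
  selector <- as_ligand_selector(selector)
  a <- structure$atom
  mask <- a$hetero & a$resname == selector$resname &
    a$chain == selector$chain & a$resseq == selector$resseq
  if (!any(mask))
    stop("ligand ", format_selector(selector), " not found among hetero groups")
  lig <- new_structure(a[mask, , drop = FALSE], source_format = structure$source_format)
  bonds <- infer_bonds(lig)
  lig <- assign_autodock_types(lig, bonds)
  ## formal-charge seed: charges already present on the atoms are honoured
  ## (they come from a generator or an annotated file); otherwise neutral
  seed <- lig$atom$charge
  seed[!is.finite(seed)] <- 0
  lig <- assign_gasteiger_charges(lig, bonds, formal = seed)
  lig <- unite_nonpolar_hydrogens(lig, bonds)
  unknown <- setdiff(unique(lig$atom$ad_type), rownames(ad4_type_params()))
  if (length(unknown) > 0)
    stop("cannot type ligand atoms (", paste(unknown, collapse = ", "),
         "); supply a prepared ligand PDBQT (advanced option) instead")
  with_class(list(atom = lig$atom, selector = selector,
                  includes_bridge_waters = FALSE),
             "abscan_ligand")
}

#' @export
print.abscan_ligand <- function(x, ...) {
  cat(sprintf("<abscan_ligand> %s: %d atoms, net charge %+.3f%s\n",
              format_selector(x$selector), nrow(x$atom), sum(x$atom$charge),
              if (isTRUE(x$includes_bridge_waters)) " (with bridge waters)" else ""))
  invisible(x)
}

#' Dump per-atom types and charges
#'
#' Debug aid: a tab-separated table of atom identity, assigned AutoDock type
#' and partial charge.
#'
#' @param x A prepared structure or ligand.
#' @param file Output path, or `""` for stdout.
#' @return Invisibly, the table.
#' @export
dump_typing <- function(x, file = "") {
  a <- if (inherits(x, "abscan_ligand")) x$atom else x$atom
  tab <- data.frame(serial = a$serial, chain = a$chain, resseq = a$resseq,
                    resname = a$resname, name = a$name, elem = a$elem,
                    ad_type = a$ad_type, charge = round(a$charge, 4))
  utils::write.table(tab, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}
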