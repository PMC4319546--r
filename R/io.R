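## PDB and PDBQT input/output.
##
## PDB records go through bio3d's fixed-width reader/writer; this module adds
## the policies the scan needs on top of it (first-MODEL-only, record-level
## validation with line numbers, highest-occupancy alt-loc resolution).  The
## PDBQT dialect (partial charge in columns 71-76, AutoDock type in 78-79)
## has no established R reader, so it is parsed here directly.

#' Parse a PDB-format character stream
#'
#' @param text Character vector of PDB lines, or a single string containing
#'   newlines.
#' @param title Optional title stored on the result.
#' @return An [new_structure()] object. Only the first MODEL of a multi-model
#'   file is kept (with a warning); alternate locations are resolved to the
#'   highest-occupancy conformer (alphabetical alt-loc id on ties); elements
#'   are taken from columns 77-78 or inferred from the atom name.
#' @export
parse_pdb <- function(text, title = "") {
  lines <- split_lines(text)
  lines <- first_model_only(lines)
  is_coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_coord)) stop("no coordinate (ATOM/HETATM) records found")
  bad <- which(is_coord & !coord_fields_ok(lines))
  if (length(bad) > 0) {
    warning("skipping ", length(bad), " malformed coordinate record(s), ",
            "first at line ", bad[1])
    lines <- lines[-bad]
    if (!any(grepl("^(ATOM  |HETATM)", lines)))
      stop("no well-formed coordinate records found")
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, rm.alt = FALSE,
                         rm.insert = FALSE, verbose = FALSE)
  from_bio3d(pdb, title = title)
}

#' Read a PDB file
#'
#' @param file Path to a PDB file.
#' @return An [new_structure()] object; see [parse_pdb()].
#' @export
read_pdb <- function(file) {
  parse_pdb(readLines(file, warn = FALSE), title = basename(file))
}

#' Download a PDB entry from the RCSB
#'
#' Convenience for case studies; requires network access.
#'
#' @param id Four-character PDB identifier.
#' @param path Directory to store the file in.
#' @return The downloaded file path, invisibly usable with [read_pdb()].
#' @export
fetch_pdb <- function(id, path = tempdir()) {
  id <- toupper(id)
  dest <- file.path(path, paste0(id, ".pdb"))
  if (!file.exists(dest)) {
    url <- paste0("https://files.rcsb.org/download/", id, ".pdb")
    utils::download.file(url, dest, quiet = TRUE)
  }
  invisible(dest)
}

split_lines <- function(text) {
  if (length(text) == 1 && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  text
}

## Keep only the first MODEL block of a multi-model file: coordinate records
## after the first ENDMDL are dropped; non-coordinate records are kept.
first_model_only <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) <= 1) return(lines)
  warning("multi-MODEL file: keeping the first model only")
  ends <- grep("^ENDMDL", lines)
  cut <- if (length(ends) > 0) ends[1] else starts[2]
  after <- lines[seq_along(lines) > cut]
  keep_after <- after[!grepl("^(ATOM  |HETATM|MODEL|ENDMDL|ANISOU|TER)", after)]
  c(lines[seq_len(cut - 1L)][!grepl("^MODEL", lines[seq_len(cut - 1L)])], keep_after)
}

## TRUE where the fixed-width numeric fields of a coordinate record parse.
coord_fields_ok <- function(lines) {
  x <- suppressWarnings(as.numeric(substr(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(lines, 47, 54)))
  nchar(lines) >= 54 & !is.na(x) & !is.na(y) & !is.na(z)
}

## bio3d pdb object -> abscan structure, with alt-loc resolution.
from_bio3d <- function(pdb, title = "") {
  a <- pdb$atom
  blank <- function(v) ifelse(is.na(v), "", trimws(as.character(v)))
  occ <- suppressWarnings(as.numeric(a$o))
  occ[!is.finite(occ)] <- 1
  elem <- norm_elem(blank(a$elesy))
  need <- elem == ""
  if (any(need)) elem[need] <- guess_element(a$elety[need])
  atom <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    alt = blank(a$alt),
    resname = trimws(a$resid),
    chain = blank(a$chain),
    resseq = as.integer(a$resno),
    icode = blank(a$insert),
    x = a$x, y = a$y, z = a$z,
    occ = pmin(pmax(occ, 0), 1),
    elem = elem,
    hetero = a$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atom <- resolve_altloc(atom)
  new_structure(atom, title = title, source_format = "pdb")
}

## Keep one conformer per atom: highest occupancy, alphabetical alt id on ties.
resolve_altloc <- function(atom) {
  key <- paste(atom$chain, atom$resseq, atom$icode, atom$name, sep = "\r")
  ord <- order(key, -atom$occ, atom$alt)
  keep <- sort(ord[!duplicated(key[ord])])
  atom[keep, , drop = FALSE]
}

#' Write a structure as PDB
#'
#' @param structure An `abscan_structure`.
#' @param file Output path, or `NULL` to return the lines.
#' @return Invisibly, the PDB lines. Round-trips through [parse_pdb()]:
#'   atom count, names, residue ids and coordinates (3 decimals) are
#'   preserved.
#' @export
write_pdb <- function(structure, file = NULL) {
  a <- structure$atom
  tmp <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(
    file = tmp,
    type = ifelse(a$hetero, "HETATM", "ATOM"),
    eleno = a$serial,
    elety = a$name,
    resid = a$resname,
    chain = a$chain,
    resno = a$resseq,
    insert = ifelse(a$icode == "", NA, a$icode),
    xyz = as.vector(t(coords(a))),
    o = a$occ,
    b = rep(0, nrow(a)),
    elesy = pdb_elem_case(a$elem)
  )
  lines <- readLines(tmp, warn = FALSE)
  if (is.null(file)) unlink(tmp)
  invisible(lines)
}

## "CL" -> "Cl" etc. for the element columns.
pdb_elem_case <- function(e) {
  ifelse(nchar(e) == 2,
         paste0(substr(e, 1, 1), tolower(substr(e, 2, 2))), e)
}

#' Parse a PDBQT-format ligand
#'
#' AutoDock4 dialect: partial charge in columns 71-76, AutoDock atom type in
#' columns 78-79. ROOT/BRANCH/ENDBRANCH/TORSDOF/REMARK records are tolerated
#' and ignored (the force field only rescores a fixed pose; the torsion tree
#' is irrelevant). Water records (HOH/WAT/DOD) are retained as ligand atoms,
#' which is how bridge waters are carried into the scoring.
#'
#' @param text Character vector of PDBQT lines (or one string with newlines).
#' @return An object of class `abscan_ligand`: the atom table (with `ad_type`
#'   and `charge` set from the file), the `selector` of the principal hetero
#'   group, and `includes_bridge_waters`.
#' @export
parse_pdbqt <- function(text) {
  lines <- split_lines(text)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no coordinate (ATOM/HETATM) records found")
  idx <- which(rec)
  ln <- lines[idx]
  q <- suppressWarnings(as.numeric(substr(ln, 71, 76)))
  ty <- trimws(substr(ln, 78, 79))
  bad <- which(nchar(ln) < 78 | is.na(q) | ty == "")
  if (length(bad) > 0)
    stop("PDBQT record without charge/type columns at line ", idx[bad[1]])
  atom <- data.frame(
    serial = as.integer(substr(ln, 7, 11)),
    name = trimws(substr(ln, 13, 16)),
    alt = trimws(substr(ln, 17, 17)),
    resname = trimws(substr(ln, 18, 21)),
    chain = trimws(substr(ln, 22, 22)),
    resseq = as.integer(substr(ln, 23, 26)),
    icode = trimws(substr(ln, 27, 27)),
    x = as.numeric(substr(ln, 31, 38)),
    y = as.numeric(substr(ln, 39, 46)),
    z = as.numeric(substr(ln, 47, 54)),
    occ = {
      o <- suppressWarnings(as.numeric(substr(ln, 55, 60)))
      ifelse(is.finite(o), pmin(pmax(o, 0), 1), 1)
    },
    hetero = TRUE,
    ad_type = ty,
    charge = q,
    stringsAsFactors = FALSE
  )
  atom$elem <- ad_to_element(ty, atom$name)
  known <- rownames(ad4_type_params())
  if (!all(atom$ad_type %in% known))
    warning("PDBQT contains AD type(s) without force-field parameters: ",
            paste(unique(setdiff(atom$ad_type, known)), collapse = ", "))
  waters <- atom$resname %in% WATER_NAMES
  main <- atom[!waters, , drop = FALSE]
  sel_row <- if (nrow(main) > 0) main[1, ] else atom[1, ]
  structure(list(
    atom = atom,
    selector = ligand_selector(sel_row$resname, sel_row$chain, sel_row$resseq),
    includes_bridge_waters = any(waters)
  ), class = "abscan_ligand")
}

## AD type -> element (for radii lookups on PDBQT input).
ad_to_element <- function(ad, name) {
  e <- c(C = "C", A = "C", N = "N", "NA" = "N", OA = "O", SA = "S", S = "S",
         HD = "H", H = "H", F = "F", Cl = "CL", Br = "BR", I = "I",
         P = "P", W = "O")[ad]
  ifelse(is.na(e), guess_element(name), e)
}

#' Read a PDBQT ligand file
#'
#' @param file Path to a PDBQT file.
#' @return See [parse_pdbqt()].
#' @export
read_pdbqt <- function(file) parse_pdbqt(readLines(file, warn = FALSE))

#' Write a prepared structure or ligand as PDBQT
#'
#' @param x An `abscan_structure` or `abscan_ligand` whose atoms carry
#'   `ad_type` and `charge`.
#' @param file Output path, or `NULL` to return the lines.
#' @return Invisibly, the PDBQT lines.
#' @export
write_pdbqt <- function(x, file = NULL) {
  a <- if (inherits(x, "abscan_ligand")) x$atom else x$atom
  if (any(is.na(a$ad_type)) || any(!is.finite(a$charge)))
    stop("atoms must carry AD types and charges before PDBQT export")
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  lines <- sprintf("%-6s%5d %4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
                   ifelse(a$hetero, "HETATM", "ATOM"),
                   a$serial %% 100000, name4, substr(a$alt, 1, 1),
                   a$resname, ifelse(a$chain == "", " ", a$chain),
                   a$resseq %% 10000, ifelse(a$icode == "", " ", a$icode),
                   a$x, a$y, a$z, a$occ, 0, a$charge, a$ad_type)
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
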