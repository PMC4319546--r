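## The full scan: site selection -> per-residue alanine mutation ->
## rescoring -> ddG ranking -> hotspot calls -> reports.

#' Default scan configuration
#'
#' @param cutoff Binding-site distance cutoff, Angstrom. Default 4.5.
#' @param threshold Hotspot ddG threshold, kcal/mol. Default 0.5.
#' @param minimize Run local clash-relief minimisation on each mutant.
#'   Default `FALSE`: truncation cannot introduce new contacts.
#' @param seed Integer seed (used by the minimiser's annealing stage).
#' @param params Force-field constants, [scoring_params()].
#' @return A configuration list for [alanine_scan()].
#' @export
scan_config <- function(cutoff = 4.5, threshold = 0.5, minimize = FALSE,
                        seed = 1, params = scoring_params()) {
  list(cutoff = cutoff, threshold = threshold, minimize = minimize,
       seed = as.integer(seed), params = params)
}

#' Alanine scan of a protein-ligand binding site
#'
#' For every receptor residue within `config$cutoff` of the ligand: truncate
#' it to alanine, rescore the complex, and record
#' ddG = E_mut - E_wt (so a residue whose side chain makes favourable,
#' negative interaction energy yields a positive ddG; large positive values
#' mark candidate loss-of-function mutations). ALA and GLY residues appear
#' as skipped records. The wild type is scored once; each mutant is scored
#' against the identical ligand pose.
#'
#' @param complex An `abscan_structure` containing receptor and ligand.
#' @param ligand A ligand selector (`"RESNAME:CHAIN:RESSEQ"` or
#'   [ligand_selector()]) to be prepared natively from the complex, or a
#'   pre-prepared `abscan_ligand` (e.g. from [read_pdbqt()], which may carry
#'   bridge waters and user-set charges).
#' @param config [scan_config()].
#' @return An object of class `abscan_scan`: `records` (data.frame sorted
#'   by ddG descending, ties by residue id), `cutoff`, `threshold`,
#'   `ligand` selector, `E_wt` breakdown, `mutants` (the mutant structures,
#'   by residue id), and `provenance`.
#' @export
alanine_scan <- function(complex, ligand, config = scan_config()) {
  lig <- if (inherits(ligand, "abscan_ligand")) ligand
         else prepare_ligand(complex, ligand)
  receptor <- prepare_receptor(complex)
  site <- select_binding_site(receptor, lig, cutoff = config$cutoff)
  E_wt <- interaction_energy(receptor, lig, config$params)
  recs <- list()
  mutants <- list()
  sres <- site$residues
  for (k in seq_len(nrow(sres))) {
    id <- sres$res_id[k]
    mut <- mutate_to_alanine(receptor, id, ligand = lig)
    if (!isFALSE(mut$skipped)) {
      recs[[k]] <- scan_record(id, sres$resname[k], sres$min_distance[k],
                               skipped = mut$skipped)
      next
    }
    if (isTRUE(config$minimize))
      mut <- minimize_local(mut, seed = config$seed)
    E_mut <- interaction_energy(mut$structure, lig, config$params)
    q <- model_quality(mut)
    recs[[k]] <- scan_record(id, sres$resname[k], sres$min_distance[k],
                             E_wt = E_wt, E_mut = E_mut, quality = q)
    mutants[[id]] <- mut$structure
  }
  records <- do.call(rbind, recs)
  if (is.null(records)) records <- scan_record_empty()
  ## rank: ddG descending, skipped records last, ties by residue id
  ord <- order(records$skipped,
               -ifelse(is.na(records$ddG), -Inf, records$ddG),
               records$res_id, method = "radix")
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  out <- structure(list(
    records = records, cutoff = config$cutoff, threshold = config$threshold,
    ligand = lig$selector, E_wt = E_wt, mutants = mutants,
    provenance = list(
      package = "abscan",
      version = as.character(utils::packageVersion("abscan")),
      cutoff = config$cutoff, threshold = config$threshold,
      minimize = isTRUE(config$minimize), seed = config$seed,
      ligand = format_selector(lig$selector),
      bridge_waters = isTRUE(lig$includes_bridge_waters),
      model_quality_metric = "steric-clash count (no statistical potential)"
    )
  ), class = "abscan_scan")
  classify_hotspots(out, threshold = config$threshold)
}

scan_record <- function(id, resname, min_distance, E_wt = NULL, E_mut = NULL,
                        quality = NULL, skipped = FALSE) {
  if (!isFALSE(skipped)) {
    return(data.frame(res_id = id, resname = resname,
                      min_distance = min_distance,
                      E_wt = NA_real_, E_mut = NA_real_, ddG = NA_real_,
                      d_vdw = NA_real_, d_hbond = NA_real_, d_elec = NA_real_,
                      d_desolv = NA_real_, n_clashes = NA_integer_,
                      hotspot = NA, skipped = TRUE,
                      skip_reason = as.character(skipped),
                      stringsAsFactors = FALSE))
  }
  data.frame(res_id = id, resname = resname, min_distance = min_distance,
             E_wt = E_wt$total, E_mut = E_mut$total,
             ddG = E_mut$total - E_wt$total,
             d_vdw = E_mut$vdw - E_wt$vdw,
             d_hbond = E_mut$hbond - E_wt$hbond,
             d_elec = E_mut$elec - E_wt$elec,
             d_desolv = E_mut$desolv - E_wt$desolv,
             n_clashes = quality$n_clashes,
             hotspot = NA, skipped = FALSE, skip_reason = "",
             stringsAsFactors = FALSE)
}

scan_record_empty <- function() {
  scan_record("x", "x", 0, skipped = "x")[0, ]
}

#' Flag hotspot residues
#'
#' A residue is a hotspot iff its ddG meets or exceeds the threshold
#' (`>=` comparison, so a ddG exactly at the threshold is a hotspot).
#'
#' @param result An `abscan_scan`.
#' @param threshold kcal/mol; default 0.5.
#' @return The result with the `hotspot` flags and `threshold` updated.
#' @export
classify_hotspots <- function(result, threshold = 0.5) {
  result$records$hotspot <- ifelse(result$records$skipped, NA,
                                   result$records$ddG >= threshold)
  result$threshold <- threshold
  result$provenance$threshold <- threshold
  result
}

#' Summary statistics of a scan
#'
#' @param result An `abscan_scan`.
#' @return A list: `n_residues` (scored), `n_skipped`, `mean_ddG`,
#'   `max_ddG`, `n_hotspots`, `hotspot_fraction` — or an empty list if
#'   nothing was scored.
#' @export
site_summary <- function(result) {
  r <- result$records[!result$records$skipped, , drop = FALSE]
  if (nrow(r) == 0) return(list())
  list(n_residues = nrow(r),
       n_skipped = sum(result$records$skipped),
       mean_ddG = mean(r$ddG),
       max_ddG = max(r$ddG),
       n_hotspots = sum(r$hotspot),
       hotspot_fraction = mean(r$hotspot))
}

#' @export
print.abscan_scan <- function(x, ...) {
  cat(sprintf("<abscan_scan> ligand %s, cutoff %.2f A, threshold %.2f kcal/mol\n",
              format_selector(x$ligand), x$cutoff, x$threshold))
  cat(sprintf("  E_wt = %.3f kcal/mol; %d residue(s), %d skipped, %d hotspot(s)\n",
              x$E_wt$total, nrow(x$records), sum(x$records$skipped),
              sum(x$records$hotspot, na.rm = TRUE)))
  print(utils::head(x$records[, c("res_id", "resname", "ddG", "hotspot",
                                  "skipped")], 10))
  invisible(x)
}

#' Write scan reports
#'
#' Emits, under `out_dir`: `scan.csv` (one row per site residue, ranked,
#' with per-term deltas; skipped residues flagged), `scan.json` (records
#' plus full provenance), `mutants/<res>.pdb` (each mutant model), and
#' `color_ddG.pml` (a PyMOL script colouring binding-site residues on a
#' red-to-blue gradient from the highest to the lowest ddG).
#'
#' @param result An `abscan_scan`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  paths <- c(csv = file.path(out_dir, "scan.csv"),
             json = file.path(out_dir, "scan.json"),
             pml = file.path(out_dir, "color_ddG.pml"))
  utils::write.csv(result$records, paths["csv"], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(provenance = result$provenance,
         E_wt = unclass(result$E_wt),
         summary = site_summary(result),
         records = result$records),
    paths["json"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mut_dir <- file.path(out_dir, "mutants")
  dir.create(mut_dir, showWarnings = FALSE)
  for (id in names(result$mutants)) {
    safe <- gsub(":", "_", id)
    write_pdb(result$mutants[[id]], file.path(mut_dir, paste0(safe, ".pdb")))
  }
  writeLines(coloring_script(result), paths["pml"])
  invisible(paths)
}

## PyMOL commands mapping ddG onto a red (high) - white - blue (low) ramp.
coloring_script <- function(result) {
  r <- result$records[!result$records$skipped, , drop = FALSE]
  lines <- c("# color binding-site residues by ddG (red = high, blue = low)",
             "hide everything", "show cartoon", "color grey80")
  if (nrow(r) == 0) return(lines)
  lo <- min(r$ddG); hi <- max(r$ddG)
  span <- if (hi > lo) hi - lo else 1
  for (k in seq_len(nrow(r))) {
    f <- (r$ddG[k] - lo) / span            # 0 = blue, 1 = red
    rgb <- grDevices::rgb(f, 1 - abs(2 * f - 1) * 0.5, 1 - f)
    p <- parse_res_id(r$res_id[k])
    lines <- c(lines, sprintf("color 0x%s, chain %s and resi %d%s",
                              substr(rgb, 2, 7), p$chain, p$resseq,
                              if (nzchar(p$icode)) p$icode else ""))
  }
  c(lines, "show sticks, hetatm")
}
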