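# Shared builders: everything is generated in code, nothing is read from disk.

# One fixed-width PDB coordinate line.
pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     occ = 1, alt = "", icode = "", het = FALSE, elem = NULL) {
  if (is.null(elem)) elem <- substr(gsub("[0-9]", "", name), 1, 1)
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, name4,
          if (alt == "") " " else alt, resname, chain, resseq,
          if (icode == "") " " else icode, x, y, z, occ, 0, elem)
}

# One PDBQT coordinate line (charge in 71-76, AD type in 78-79).
pdbqt_line <- function(serial, name, resname, chain, resseq, x, y, z,
                      charge, ad_type, het = TRUE) {
  name4 <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          if (het) "HETATM" else "ATOM", serial, name4, resname, chain,
          resseq, x, y, z, 1, 0, charge, ad_type)
}

# A bare atom table row; defaults make a receptor carbon at the origin.
atom_row <- function(serial, name = "C", x = 0, y = 0, z = 0, elem = "C",
                     resname = "GLY", chain = "A", resseq = 1L, het = FALSE,
                     ad_type = NA_character_, charge = NA_real_, occ = 1) {
  data.frame(serial = serial, name = name, alt = "", resname = resname,
             chain = chain, resseq = as.integer(resseq), icode = "",
             x = x, y = y, z = z, occ = occ, elem = elem, hetero = het,
             ad_type = ad_type, charge = charge, stringsAsFactors = FALSE)
}

# Idealised all-atom ethanol: CH3-CH2-OH, 9 atoms, 8 bonds.
ethanol_structure <- function() {
  at <- rbind(
    atom_row(1, "C1", 0, 0, 0, "C", resname = "EOH", het = TRUE),
    atom_row(2, "C2", 1.530, 0, 0, "C", resname = "EOH", het = TRUE),
    atom_row(3, "O1", 2.001, 1.329, 0, "O", resname = "EOH", het = TRUE),
    atom_row(4, "H11", -0.363, 1.028, 0, "H", resname = "EOH", het = TRUE),
    atom_row(5, "H12", -0.363, -0.513, 0.890, "H", resname = "EOH", het = TRUE),
    atom_row(6, "H13", -0.363, -0.513, -0.890, "H", resname = "EOH", het = TRUE),
    atom_row(7, "H21", 1.893, -0.513, 0.890, "H", resname = "EOH", het = TRUE),
    atom_row(8, "H22", 1.893, -0.513, -0.890, "H", resname = "EOH", het = TRUE),
    atom_row(9, "HO1", 2.935, 1.474, 0, "H", resname = "EOH", het = TRUE)
  )
  new_structure(at)
}

# All-atom methane with tetrahedral hydrogens.
methane_structure <- function() {
  at <- rbind(
    atom_row(1, "C1", 0, 0, 0, "C", resname = "CH4", het = TRUE),
    atom_row(2, "H1", 0.629, 0.629, 0.629, "H", resname = "CH4", het = TRUE),
    atom_row(3, "H2", -0.629, -0.629, 0.629, "H", resname = "CH4", het = TRUE),
    atom_row(4, "H3", -0.629, 0.629, -0.629, "H", resname = "CH4", het = TRUE),
    atom_row(5, "H4", 0.629, -0.629, -0.629, "H", resname = "CH4", het = TRUE)
  )
  new_structure(at)
}

# Random prepared receptor/ligand pair for brute-force comparisons: types
# drawn from the parameter table, charges uniform in [-0.5, 0.5].
random_scoring_fixture <- function(n_rec = 100, n_lig = 20, seed = 42,
                                   box = 12) {
  set.seed(seed)
  types <- rownames(ad4_type_params())
  rec <- do.call(rbind, lapply(seq_len(n_rec), function(i)
    atom_row(i, paste0("X", i), runif(1, 0, box), runif(1, 0, box),
             runif(1, 0, box), elem = "C", resseq = i,
             ad_type = sample(types, 1), charge = runif(1, -0.5, 0.5))))
  lig <- do.call(rbind, lapply(seq_len(n_lig), function(i)
    atom_row(n_rec + i, paste0("Y", i), runif(1, 0, box), runif(1, 0, box),
             runif(1, 0, box), elem = "C", resname = "LIG", chain = "X",
             resseq = 900L, het = TRUE,
             ad_type = sample(types, 1), charge = runif(1, -0.5, 0.5))))
  list(receptor = new_structure(rec),
       ligand = structure(list(atom = lig,
                               selector = ligand_selector("LIG", "X", 900),
                               includes_bridge_waters = FALSE),
                          class = "abscan_ligand"))
}

# Plain double-loop oracle for the intermolecular energy: scalar term calls,
# H-bond pairs take the 12-10 term instead of the 12-6.
brute_force_energy <- function(receptor, ligand, params = scoring_params()) {
  ra <- receptor$atom; la <- ligand$atom
  t <- params$types
  vdw <- hb <- el <- ds <- 0
  for (i in seq_len(nrow(ra))) {
    for (j in seq_len(nrow(la))) {
      r <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                  (ra$z[i] - la$z[j])^2)
      if (r > params$nb_cutoff) next
      ti <- ra$ad_type[i]; tj <- la$ad_type[j]
      hb_pair <- (t[ti, "hbond"] == "donor" & t[tj, "hbond"] == "acceptor") ||
        (t[ti, "hbond"] == "acceptor" & t[tj, "hbond"] == "donor")
      if (hb_pair) hb <- hb + hbond_energy(r, ti, tj, params)
      else vdw <- vdw + vdw_energy(r, ti, tj, params)
      el <- el + elec_energy(r, ra$charge[i], la$charge[j], params)
      ds <- ds + desolv_energy(r, ti, tj, ra$charge[i], la$charge[j], params)
    }
  }
  params$W_vdw * vdw + params$W_hb * hb + params$W_elec * el + params$W_sol * ds
}

# A small mixed-residue complex with a two-contact site, reused across tests.
default_toy <- function(seed = 1) {
  make_toy_complex(toy_spec(
    8, c("LEU", "SER", "TRP", "GLY", "ASP", "PHE", "LYS", "ALA"),
    contact_residues = c(3, 5), seed = seed))
}
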