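# Bond perception, AutoDock typing, PEOE charges, hydrogen handling.

test_that("bond perception follows covalent distances", {
  two_c <- function(d) new_structure(rbind(atom_row(1, "C1"),
                                           atom_row(2, "C2", x = d, resseq = 2)))
  expect_equal(nrow(infer_bonds(two_c(1.54))$edges), 1)
  expect_equal(nrow(infer_bonds(two_c(4.0))$edges), 0)
  expect_equal(nrow(infer_bonds(ethanol_structure())$edges), 8)
})

test_that("hydrogens keep exactly one bond, to the nearest heavy atom", {
  b <- infer_bonds(ethanol_structure())
  elem <- ethanol_structure()$atom$elem
  h_idx <- which(elem == "H")
  deg <- tabulate(c(b$edges[, 1], b$edges[, 2]), nbins = b$n)
  expect_true(all(deg[h_idx] == 1))
})

test_that("AutoDock typing: acceptor oxygens, aromatic carbons, donor hydrogens", {
  s <- make_toy_complex(toy_spec(4, c("GLY", "SER", "PHE", "GLY")))
  b <- infer_bonds(s)
  s <- assign_autodock_types(s, b)
  a <- s$atom
  expect_equal(a$ad_type[a$name == "OG"], "OA")
  ring <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  expect_equal(a$ad_type[a$resname == "PHE" & a$name %in% ring],
               rep("A", 6))
  expect_equal(a$ad_type[a$resname == "PHE" & a$name == "CB"], "C")
  # backbone amide hydrogen (added during preparation) is a polar donor
  rec <- prepare_receptor(s)
  expect_equal(unique(rec$atom$ad_type[rec$atom$name == "H"]), "HD")
  # prepared receptor carries only parameterised types
  expect_true(all(rec$atom$ad_type %in% rownames(ad4_type_params())))
})

test_that("nitrogen acceptor rule: bare ring N is NA, amide/ammonium N is N", {
  s <- make_toy_complex(toy_spec(4, c("GLY", "HIS", "LYS", "GLY")))
  rec <- prepare_receptor(s)
  a <- rec$atom
  expect_equal(a$ad_type[a$name == "ND1"], "NA")   # unprotonated imidazole N
  expect_equal(a$ad_type[a$name == "NE2"], "N")    # protonated tautomer
  expect_equal(a$ad_type[a$name == "NZ"], "N")     # lysine ammonium
  expect_true(all(a$ad_type[a$name == "N"] == "N"))
})

test_that("PEOE charges: methane matches the published worked example", {
  s <- methane_structure()
  b <- infer_bonds(s)
  s <- assign_autodock_types(s, b)
  s <- assign_gasteiger_charges(s, b, formal = 0)
  # independently computed with Open Babel's Gasteiger implementation
  expect_equal(s$atom$charge[1], -0.0776, tolerance = 2e-3)
  expect_equal(sum(s$atom$charge), 0, tolerance = 1e-6)
})

test_that("PEOE conserves total charge and is permutation-invariant", {
  s <- ethanol_structure()
  b <- infer_bonds(s)
  s <- assign_autodock_types(s, b)
  s1 <- assign_gasteiger_charges(s, b, formal = 0)
  expect_equal(sum(s1$atom$charge), 0, tolerance = 1e-6)
  perm <- c(9, 3, 1, 5, 2, 8, 4, 7, 6)
  sp <- new_structure(s$atom[perm, ])
  bp <- infer_bonds(sp)
  sp <- assign_autodock_types(sp, bp)
  sp <- assign_gasteiger_charges(sp, bp, formal = 0)
  expect_equal(sp$atom$charge, s1$atom$charge[perm], tolerance = 1e-10)
})

test_that("charged groups carry their formal charge through PEOE", {
  s <- make_toy_complex(toy_spec(5, c("GLY", "ASP", "GLY", "LYS", "GLY")))
  rec <- prepare_receptor(s)
  # N-terminus +1, C-terminus 0 (no OXT written), Asp -1, Lys +1
  expect_equal(sum(rec$atom$charge), 1, tolerance = 1e-6)
  asp <- rec$atom$resname == "ASP"
  expect_lt(sum(rec$atom$charge[asp]), -0.5)
  lys <- rec$atom$resname == "LYS"
  expect_gt(sum(rec$atom$charge[lys]), 0.5)
})

test_that("uniting nonpolar hydrogens conserves charge exactly", {
  s <- methane_structure()
  b <- infer_bonds(s)
  s <- assign_autodock_types(s, b)
  s <- assign_gasteiger_charges(s, b, formal = 0)
  total_before <- sum(s$atom$charge)
  u <- unite_nonpolar_hydrogens(s, b)
  expect_equal(nrow(u$atom), 1)
  expect_equal(u$atom$elem, "C")
  expect_equal(sum(u$atom$charge), total_before, tolerance = 1e-12)

  e <- ethanol_structure()
  be <- infer_bonds(e)
  e <- assign_autodock_types(e, be)
  e <- assign_gasteiger_charges(e, be, formal = 0)
  ue <- unite_nonpolar_hydrogens(e, be)
  expect_true("HO1" %in% ue$atom$name)              # polar H retained
  expect_false(any(grepl("^H[12]", ue$atom$name)))  # carbon H merged
  expect_equal(sum(ue$atom$charge), sum(e$atom$charge), tolerance = 1e-12)
})

test_that("check_hydrogens adds missing polar hydrogens at ideal geometry and is idempotent", {
  s <- make_toy_complex(toy_spec(3, c("GLY", "SER", "GLY")))
  b <- infer_bonds(s)
  s <- assign_autodock_types(s, b)
  h <- check_hydrogens(s, b)
  ser <- h$atom[h$atom$resname == "SER", ]
  expect_true("HG" %in% ser$name)
  og <- ser[ser$name == "OG", c("x", "y", "z")]
  hg <- ser[ser$name == "HG", c("x", "y", "z")]
  expect_equal(sqrt(sum((og - hg)^2)), 0.96, tolerance = 1e-6)
  # amide H on every residue after the first (GLY 1 is the N-terminus)
  expect_true(all(c("H") %in% h$atom$name[h$atom$resseq %in% 2:3]))
  # idempotent: a second pass adds nothing
  h2 <- check_hydrogens(h)
  expect_equal(nrow(h2$atom), nrow(h$atom))
})

test_that("added hydrogens are typed HD and charged by the PEOE pass", {
  s <- make_toy_complex(toy_spec(3, c("GLY", "SER", "GLY")))
  rec <- prepare_receptor(s)
  hg <- rec$atom[rec$atom$name == "HG", ]
  expect_equal(nrow(hg), 1)
  expect_equal(hg$ad_type, "HD")
  expect_gt(hg$charge, 0.1)     # hydroxyl hydrogen is distinctly positive
})
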