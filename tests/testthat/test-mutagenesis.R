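# Alanine truncation, clash metric, local minimisation.

test_that("tryptophan truncation removes exactly the side chain beyond CB", {
  s <- default_toy()
  rec <- prepare_receptor(s)
  mut <- mutate_to_alanine(rec, "A:3")
  expect_false(isTRUE(mut$skipped != FALSE))
  heavy_removed <- setdiff(mut$removed_atoms, grep("^[0-9]*H", mut$removed_atoms,
                                                  value = TRUE))
  expect_setequal(heavy_removed,
                  c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3",
                    "CH2"))
  res3 <- mut$structure$atom[mut$structure$atom$resseq == 3 &
                               !mut$structure$atom$hetero, ]
  expect_true("CB" %in% res3$name)
  expect_equal(unique(res3$resname), "ALA")
  # CB sits at the ideal 1.53 A from CA along the original direction
  ca <- as.numeric(res3[res3$name == "CA", c("x", "y", "z")])
  cb <- as.numeric(res3[res3$name == "CB", c("x", "y", "z")])
  expect_equal(sqrt(sum((cb - ca)^2)), 1.53, tolerance = 1e-9)
})

test_that("truncation never moves atoms it does not delete", {
  s <- default_toy()
  rec <- prepare_receptor(s)
  mut <- mutate_to_alanine(rec, "A:5")
  w <- rec$atom
  m <- mut$structure$atom
  common <- merge(w, m, by = c("chain", "resseq", "icode", "name"))
  common <- common[!(common$resseq == 5 & common$name == "CB"), ]
  expect_equal(common$x.x, common$x.y)
  expect_equal(common$y.x, common$y.y)
  expect_equal(common$z.x, common$z.y)
})

test_that("ALA and GLY residues signal a skip and leave the structure unchanged", {
  s <- default_toy()
  rec <- prepare_receptor(s)
  mut_ala <- mutate_to_alanine(rec, "A:8")
  expect_match(mut_ala$skipped, "alanine")
  expect_identical(mut_ala$structure$atom, rec$atom)
  mut_gly <- mutate_to_alanine(rec, "A:4")
  expect_match(mut_gly$skipped, "glycine")
})

test_that("mutant heavy-atom counts follow the residue topology table", {
  resnames <- c("SER", "THR", "VAL", "LEU", "ILE", "MET", "PHE", "TYR",
                "TRP", "ASP", "GLU", "ASN", "GLN", "LYS", "ARG", "HIS",
                "CYS")
  s <- make_toy_complex(toy_spec(length(resnames) + 2,
                                 c("GLY", resnames, "GLY")))
  topo <- list(SER = 1, THR = 2, VAL = 2, LEU = 3, ILE = 3, MET = 3,
               PHE = 6, TYR = 7, TRP = 9, ASP = 3, GLU = 4, ASN = 3,
               GLN = 4, LYS = 4, ARG = 6, HIS = 5, CYS = 1)
  heavy <- function(a) sum(a$elem != "H")
  for (k in seq_along(resnames)) {
    id <- res_id("A", k + 1)
    mut <- mutate_to_alanine(s, id)
    expect_equal(heavy(s$atom) - heavy(mut$structure$atom),
                 topo[[resnames[k]]], info = resnames[k])
  }
})

test_that("clash metric: crystal-like fixtures are clean, overlaps are flagged poor", {
  s <- default_toy()
  mut <- mutate_to_alanine(prepare_receptor(s), "A:3")
  q <- model_quality(mut)
  expect_equal(q$n_clashes, 0)
  expect_false(q$poor)

  # 2.0 A: beyond covalent range for C-C, inside 0.6x the vdW radius sum
  overlap <- new_structure(rbind(
    atom_row(1, "CA", 0, 0, 0, resname = "ALA", resseq = 1L),
    atom_row(2, "CA", 2.0, 0, 0, resname = "GLY", resseq = 3L)))
  rep <- clash_report(overlap)
  expect_equal(rep$n_clashes, 1)
  expect_gt(rep$worst_overlap, 0)
})

test_that("minimisation resolves an artificial overlap, stays local, and is seed-deterministic", {
  at <- rbind(atom_row(1, "CA", 0, 0, 0, resname = "ALA", resseq = 1L),
              atom_row(2, "CA", 0.5, 0, 0, resname = "GLY", resseq = 3L),
              atom_row(3, "CA", 40, 0, 0, resname = "GLY", resseq = 9L))
  s <- new_structure(at)
  model <- list(structure = s, mutated = "A:1",
                removed_atoms = character(0),
                clash_report = clash_report(s), skipped = FALSE)
  class(model) <- "abscan_mutant"
  expect_equal(model$clash_report$n_clashes, 1)
  out <- minimize_local(model, seed = 11)
  a <- out$structure$atom
  d12 <- sqrt((a$x[1] - a$x[2])^2 + (a$y[1] - a$y[2])^2 + (a$z[1] - a$z[2])^2)
  expect_gte(d12, 1.5)
  expect_lte(out$clash_report$n_clashes, model$clash_report$n_clashes)
  # the atom beyond 5 A of the mutated residue is bitwise unchanged
  expect_identical(a$x[3], 40)
  # determinism
  out2 <- minimize_local(model, seed = 11)
  expect_identical(out$structure$atom, out2$structure$atom)
})

test_that("a clash-free model passes through minimisation untouched", {
  s <- default_toy()
  mut <- mutate_to_alanine(prepare_receptor(s), "A:5")
  out <- minimize_local(mut, seed = 3)
  expect_identical(out$structure$atom, mut$structure$atom)
  expect_true(out$minimized)
})
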