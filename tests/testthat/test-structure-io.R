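# PDB/PDBQT parsing and writing.

test_that("well-formed ATOM records are transcribed one atom per record", {
  txt <- c(pdb_line(1, "N", "ALA", "A", 1, 1.0, 2.0, 3.0),
           pdb_line(2, "CA", "ALA", "A", 1, 2.5, 2.0, 3.0))
  s <- parse_pdb(txt)
  expect_s3_class(s, "abscan_structure")
  expect_equal(nrow(s$atom), 2)
  expect_equal(s$atom$name, c("N", "CA"))
  expect_equal(s$atom$x, c(1.0, 2.5))
  expect_equal(unique(residue_uid <- paste(s$atom$chain, s$atom$resseq)), "A 1")
  expect_false(any(s$atom$hetero))
})

test_that("alt-locs resolve to the highest-occupancy conformer", {
  txt <- c(pdb_line(1, "CA", "SER", "A", 5, 0, 0, 0, occ = 0.60, alt = "A"),
           pdb_line(2, "CA", "SER", "A", 5, 9, 9, 9, occ = 0.40, alt = "B"),
           pdb_line(3, "CB", "SER", "A", 5, 1, 0, 0))
  s <- parse_pdb(txt)
  expect_equal(nrow(s$atom), 2)
  ca <- s$atom[s$atom$name == "CA", ]
  expect_equal(ca$x, 0)        # the 0.60 conformer
  # equal occupancy: alphabetical alt id wins, count never increases
  txt2 <- c(pdb_line(1, "CA", "SER", "A", 5, 7, 0, 0, occ = 0.50, alt = "B"),
            pdb_line(2, "CA", "SER", "A", 5, 4, 0, 0, occ = 0.50, alt = "A"))
  s2 <- parse_pdb(txt2)
  expect_equal(nrow(s2$atom), 1)
  expect_equal(s2$atom$x, 4)
})

test_that("parser policies: no coordinates errors, bad records skip with a warning, extra records ignored", {
  expect_error(parse_pdb("HEADER    NOTHING HERE"), "no coordinate")
  bad <- c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
           "ATOM      2  CB  GLY A   1      xx.xxx   0.000   0.000  1.00  0.00           C")
  expect_warning(s <- parse_pdb(bad), "malformed")
  expect_equal(nrow(s$atom), 1)
  txt <- c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
           "TER", "CONECT    1    2",
           paste0(pdb_line(2, "O", "HOH", "A", 2, 5, 5, 5, het = TRUE), "   "))
  s2 <- parse_pdb(txt)
  expect_equal(nrow(s2$atom), 2)
  expect_true(s2$atom$hetero[2])
})

test_that("only the first MODEL of a multi-model file is kept", {
  txt <- c("MODEL        1",
           pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
           "ENDMDL",
           "MODEL        2",
           pdb_line(1, "CA", "GLY", "A", 1, 9, 9, 9),
           "ENDMDL")
  expect_warning(s <- parse_pdb(txt), "first model")
  expect_equal(nrow(s$atom), 1)
  expect_equal(s$atom$x, 0)
})

test_that("write_pdb round-trips atom inventory and coordinates to 3 decimals", {
  s <- default_toy()
  lines <- write_pdb(s)
  s2 <- parse_pdb(lines)
  expect_equal(nrow(s2$atom), nrow(s$atom))
  expect_equal(s2$atom$name, s$atom$name)
  expect_equal(s2$atom$resname, s$atom$resname)
  expect_equal(s2$atom$resseq, s$atom$resseq)
  expect_equal(s2$atom$chain, s$atom$chain)
  expect_equal(s2$atom$x, round(s$atom$x, 3))
  expect_equal(s2$atom$y, round(s$atom$y, 3))
  expect_equal(s2$atom$z, round(s$atom$z, 3))
  expect_equal(s2$atom$hetero, s$atom$hetero)
})

test_that("a truncated mutant writes out with residue name ALA", {
  s <- default_toy()
  rec <- prepare_receptor(s)
  mut <- mutate_to_alanine(rec, "A:3")     # the tryptophan
  lines <- write_pdb(mut$structure)
  s2 <- parse_pdb(lines)
  expect_equal(unique(s2$atom$resname[s2$atom$resseq == 3]), "ALA")
  expect_false("CG" %in% s2$atom$name[s2$atom$resseq == 3])
})

test_that("PDBQT parsing reads charges and types verbatim", {
  txt <- c("ROOT",
           pdbqt_line(1, "O1", "LIG", "A", 500, 0, 0, 0, -0.36, "OA"),
           pdbqt_line(2, "H1", "LIG", "A", 500, 0.96, 0, 0, 0.18, "HD"),
           pdbqt_line(3, "H2", "LIG", "A", 500, -0.24, 0.93, 0, 0.18, "HD"),
           "ENDROOT", "TORSDOF 0")
  lig <- parse_pdbqt(txt)
  expect_s3_class(lig, "abscan_ligand")
  expect_equal(lig$atom$charge, c(-0.36, 0.18, 0.18))
  expect_equal(lig$atom$ad_type, c("OA", "HD", "HD"))
  expect_equal(sum(lig$atom$charge), 0, tolerance = 1e-12)
  expect_false(lig$includes_bridge_waters)
})

test_that("appended waters become bridge waters scored as ligand atoms", {
  base <- c(pdbqt_line(1, "C1", "LIG", "A", 500, 0, 0, 0, 0.05, "C"),
            pdbqt_line(2, "O1", "LIG", "A", 500, 1.2, 0, 0, -0.05, "OA"))
  wat <- vapply(1:4, function(k)
    pdbqt_line(10 + k, "O", "HOH", "A", 600 + k, 5 + k, 0, 0, -0.41, "OA"),
    character(1))
  lig <- parse_pdbqt(c(base, wat))
  expect_true(lig$includes_bridge_waters)
  expect_equal(nrow(lig$atom), 6)
  expect_equal(lig$selector$resname, "LIG")   # waters never name the ligand
})

test_that("BRANCH records do not affect the parsed atom list", {
  atoms <- c(pdbqt_line(1, "C1", "LIG", "A", 1, 0, 0, 0, 0.1, "C"),
             pdbqt_line(2, "C2", "LIG", "A", 1, 1.5, 0, 0, -0.1, "C"))
  with_tree <- c("ROOT", atoms[1], "ENDROOT", "BRANCH 1 2", atoms[2],
                 "ENDBRANCH 1 2", "TORSDOF 1")
  expect_identical(parse_pdbqt(with_tree)$atom, parse_pdbqt(atoms)$atom)
})

test_that("PDBQT records missing charge or type columns are a format error", {
  short <- "HETATM    1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00"
  expect_error(parse_pdbqt(short), "line 1")
})

test_that("write_pdbqt output re-parses to the same charges and types", {
  f <- make_pair_fixture("OA", "HD", 1.9, -0.3, 0.3)
  lines <- write_pdbqt(f$ligand)
  lig <- parse_pdbqt(lines)
  expect_equal(lig$atom$charge, 0.3)
  expect_equal(lig$atom$ad_type, "HD")
})
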