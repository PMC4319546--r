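# The four energy terms and the pairwise intermolecular sum.

params <- scoring_params()
tp <- ad4_type_params()

test_that("12-6 vdW term: analytic minimum, closed form, cutoff", {
  rij <- tp["C", "Rii"]                       # C-C pair: Rij = Rii
  eps <- tp["C", "eps"]
  expect_equal(vdw_energy(rij, "C", "C", params), -eps, tolerance = 1e-12)
  # hand-evaluated A/r^12 - B/r^6 at r = 2 Rij (smoothed distance r - 0.25)
  r <- 2 * rij
  rs <- r - params$smoothing_width / 2
  expect_equal(vdw_energy(r, "C", "C", params),
               eps * rij^12 / rs^12 - 2 * eps * rij^6 / rs^6,
               tolerance = 1e-12)
  expect_equal(vdw_energy(8.001, "C", "C", params), 0)
  # mixing rules across unlike pairs: minimum -sqrt(eps_i eps_j) at mean Rii
  rij_on <- (tp["OA", "Rii"] + tp["N", "Rii"]) / 2
  expect_equal(vdw_energy(rij_on, "OA", "N", params),
               -sqrt(tp["OA", "eps"] * tp["N", "eps"]), tolerance = 1e-12)
  # short-range ceiling
  expect_equal(vdw_energy(0.1, "C", "C", params), params$max_energy)
})

test_that("12-10 hydrogen bond: -5.0 kcal/mol at 1.9 A, zero off-pairs", {
  expect_equal(hbond_energy(1.9, "HD", "OA", params), -5.0, tolerance = 1e-12)
  expect_equal(hbond_energy(1.9, "OA", "HD", params), -5.0, tolerance = 1e-12)
  expect_equal(hbond_energy(1.9, "NA", "HD", params), -5.0, tolerance = 1e-12)
  expect_equal(hbond_energy(2.5, "HD", "SA", params), -1.0, tolerance = 1e-12)
  expect_equal(hbond_energy(1.9, "C", "C", params), 0)
  expect_equal(hbond_energy(1.9, "OA", "OA", params), 0)  # two acceptors
  expect_equal(hbond_energy(9.0, "HD", "OA", params), 0)
})

test_that("electrostatics: sign symmetry, zero charge, dielectric value", {
  expect_equal(elec_energy(5, 0, 0.7, params), 0)
  expect_equal(elec_energy(5, 1, -1, params), -elec_energy(5, 1, 1, params))
  # Mehler-Solmajer screening at 5 A, transcribed independently:
  # eps(5) = -8.5525 + 86.9525/(1 + 7.7839 exp(-0.003627*86.9525*5))
  expect_equal(ms_dielectric(5, params), 24.784426074535375, tolerance = 1e-9)
  expect_equal(elec_energy(5, 1, 1, params), 2.6796150050145964,
               tolerance = 1e-9)
})

test_that("desolvation: Gaussian decay and closed form", {
  e0 <- desolv_energy(1e-9, "C", "C", 0, 0, params)
  es <- desolv_energy(params$desolv_sigma, "C", "C", 0, 0, params)
  expect_equal(es / e0, exp(-0.5), tolerance = 1e-9)
  # closed form at r = 3.6 for an uncharged C-C pair
  expect_equal(desolv_energy(3.6, "C", "C", 0, 0, params),
               2 * tp["C", "solpar"] * tp["C", "vol"] * exp(-0.5),
               tolerance = 1e-12)
  expect_equal(desolv_energy(50, "C", "C", 0.3, -0.2, params), 0)
  # charge dependence enters through |q|
  expect_gt(abs(desolv_energy(3, "C", "C", 1, 1, params)),
            abs(desolv_energy(3, "C", "C", 0, 0, params)))
})

test_that("pair fixtures reproduce the analytic minima through the full scorer", {
  f <- make_pair_fixture("C", "C", tp["C", "Rii"])
  e <- interaction_energy(f$receptor, f$ligand, params)
  expect_equal(e$vdw, -params$W_vdw * tp["C", "eps"], tolerance = 1e-12)
  expect_equal(e$hbond, 0)

  g <- make_pair_fixture("HD", "OA", 1.9, 0.2, -0.2)
  eg <- interaction_energy(g$receptor, g$ligand, params)
  expect_equal(eg$hbond, -params$W_hb * 5.0, tolerance = 1e-12)
  expect_equal(eg$vdw, 0)          # H-bond pairs take the 12-10, not the 12-6
  expect_lt(eg$elec, 0)

  far <- make_pair_fixture("C", "C", 150)
  expect_equal(interaction_energy(far$receptor, far$ligand, params)$total, 0)
})

test_that("total is the exact sum of reported components", {
  f <- random_scoring_fixture(40, 10, seed = 9)
  e <- interaction_energy(f$receptor, f$ligand, params)
  expect_equal(e$total, e$vdw + e$hbond + e$elec + e$desolv, tolerance = 1e-9)
})

test_that("interaction energy equals the brute-force double loop on a 100-atom fixture", {
  f <- random_scoring_fixture(100, 20, seed = 42)
  e <- interaction_energy(f$receptor, f$ligand, params)
  expect_equal(e$total, brute_force_energy(f$receptor, f$ligand, params),
               tolerance = 1e-9)
})

test_that("pairwise additivity over disjoint receptor subsets", {
  f <- random_scoring_fixture(60, 15, seed = 5)
  a <- f$receptor$atom
  r1 <- new_structure(a[1:30, ])
  r2 <- new_structure(a[31:60, ])
  e_all <- interaction_energy(f$receptor, f$ligand, params)$total
  e_split <- interaction_energy(r1, f$ligand, params)$total +
    interaction_energy(r2, f$ligand, params)$total
  expect_equal(e_all, e_split, tolerance = 1e-9)
})

test_that("receptor/ligand role swap leaves the total unchanged", {
  f <- random_scoring_fixture(30, 30, seed = 13)
  swapped_rec <- new_structure(within(f$ligand$atom, hetero <- FALSE))
  swapped_lig <- structure(list(atom = within(f$receptor$atom, hetero <- TRUE),
                                selector = f$ligand$selector,
                                includes_bridge_waters = FALSE),
                           class = "abscan_ligand")
  e1 <- interaction_energy(f$receptor, f$ligand, params)
  e2 <- interaction_energy(swapped_rec, swapped_lig, params)
  expect_equal(e1$total, e2$total, tolerance = 1e-9)
})

test_that("atoms without types or charges are a hard error naming the atom", {
  f <- make_pair_fixture("C", "C", 4)
  f$receptor$atom$ad_type <- NA_character_
  expect_error(interaction_energy(f$receptor, f$ligand, params), "serial 1")
})
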