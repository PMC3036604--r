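test_that("pIC50 conversion matches the molar-scale definition", {
  expect_equal(to_pic50(0.00106), 8.9747, tolerance = 1e-4)
  expect_equal(to_pic50(80.5), 4.0942, tolerance = 1e-4)
  expect_equal(to_pic50(1e6), 0)
  # round trip over twelve orders of magnitude
  x <- 10^seq(-6, 6, by = 0.5)
  expect_equal(to_ic50(to_pic50(x)), x, tolerance = 1e-9)
  expect_error(to_pic50(-1), "positive")
})

test_that("activity tables load with pIC50 populated and order preserved", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_demo_activity_csv(path)
  tab <- load_activity_table(path)
  expect_identical(tab$id, c("m1", "m2", "m3"))
  expect_equal(tab$pic50, to_pic50(c(0.00106, 12, 80.5)))

  write_demo_activity_csv(path, ids = c("a", "a", "b"))
  expect_error(load_activity_table(path), "duplicate")

  write_demo_activity_csv(path, ic50 = c(1, -2, 3))
  expect_error(load_activity_table(path), "m2")
})

test_that("Lipinski filter applies strict single-violation rejection", {
  pass <- lipinski_filter(list(mw = 450, logp = 3.0, hbd_count = 2,
                               hba_count = 8))
  expect_true(pass$pass)
  expect_length(pass$violations, 0)

  fail <- lipinski_filter(list(mw = 501, logp = 3.0, hbd_count = 2,
                               hba_count = 8))
  expect_false(fail$pass)
  expect_identical(fail$violations, "mw")

  # all four at the boundary: strict inequalities, so the molecule passes
  edge <- lipinski_filter(list(mw = 500, logp = 5, hbd_count = 5,
                               hba_count = 10))
  expect_true(edge$pass)

  expect_error(lipinski_filter(list(mw = 400, logp = 2, hbd_count = 1)),
               "hba_count")
})

test_that("Lipinski monotonicity: raising a descriptor never rescues a failure", {
  base <- list(mw = 510, logp = 4, hbd_count = 3, hba_count = 6)
  expect_false(lipinski_filter(base)$pass)
  for (f in names(base)) {
    worse <- base
    worse[[f]] <- worse[[f]] + 100
    expect_false(lipinski_filter(worse)$pass)
  }
})

test_that("descriptors match known molecules", {
  d <- compute_descriptors(c(water = "O", benzene = "c1ccccc1",
                             ethanol = "CCO"))
  expect_equal(d$hbd_count, c(1, 0, 1))
  expect_equal(d$hba_count[2], 0)
  expect_gte(d$hba_count[1], 1)
  # atomic-mass sum for ethanol C2H6O
  expect_equal(d$mw[3], 2 * 12.011 + 6 * 1.008 + 15.999, tolerance = 0.01)
  expect_error(compute_descriptors("not-a-smiles", id = "bad"), "bad")
})

test_that("conformer ensembles respect count, window and determinism", {
  rigid <- generate_conformers("c1ccccc1", seed = 5, id = "benzene")
  expect_length(rigid$conformers, 1)
  expect_equal(rigid$rel_energies, 0)

  flex <- generate_conformers("CCCCCCCC", max_conformers = 50,
                              energy_window = 20, seed = 5, id = "octane")
  expect_lte(length(flex$conformers), 50)
  expect_gt(length(flex$conformers), 1)
  expect_true(all(flex$rel_energies >= 0 & flex$rel_energies <= 20))
  expect_equal(min(flex$rel_energies), 0)

  flex2 <- generate_conformers("CCCCCCCC", max_conformers = 50,
                               energy_window = 20, seed = 5, id = "octane")
  expect_identical(flex$conformers, flex2$conformers)
  expect_identical(flex$rel_energies, flex2$rel_energies)

  expect_error(generate_conformers("CCO", max_conformers = 0), "max_conformers")
})

test_that("duplicate geometries are removed from ensembles", {
  flex <- generate_conformers("CCCC", seed = 2, id = "butane",
                              dedup_rmsd = 0.5)
  if (length(flex$conformers) > 1) {
    combos <- combn(length(flex$conformers), 2)
    for (j in seq_len(ncol(combos))) {
      a <- flex$conformers[[combos[1, j]]]
      b <- flex$conformers[[combos[2, j]]]
      expect_gte(kabsch_align(a, b)$rmsd, 0.5)
    }
  } else {
    succeed()
  }
})
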