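# small helper: training set of pseudo-ligands with prescribed pIC50
tiny_ts <- function(hy, pic50, jitter = 0, seed = 1, uncertainty = 3) {
  set.seed(seed)
  recs <- lapply(seq_along(pic50), function(i) {
    pts <- points_on_centers(hy)
    pts[, c("x", "y", "z")] <- pts[, c("x", "y", "z")] +
      matrix(rnorm(nrow(pts) * 3, 0, jitter), ncol = 3)
    pseudo_ligand(sprintf("t%02d", i), list(pts))
  })
  training_set(recs, pic50, uncertainty = uncertainty, override = TRUE)
}

test_that("training sets enforce size, span and uncertainty rules", {
  hy <- make_pharmacophore(3, seed = 1)
  expect_error(tiny_ts(hy, seq(4, 9, length.out = 10), uncertainty = 1),
               "uncertainty")
  recs <- lapply(1:10, function(i)
    pseudo_ligand(paste0("r", i), list(points_on_centers(hy))))
  expect_error(training_set(recs, seq(4, 9, length.out = 10)), "16")
  recs16 <- lapply(1:16, function(i)
    pseudo_ligand(paste0("r", i), list(points_on_centers(hy))))
  expect_error(training_set(recs16, seq(5, 8, length.out = 16)), "span")
  expect_s3_class(training_set(recs16, seq(5, 8, length.out = 16),
                               override = TRUE), "training_set")
})

test_that("activity partition follows the uncertainty-squared and 10^3.5 rules", {
  hy <- make_pharmacophore(3, seed = 2)
  # min IC50 = 0.001 uM; 0.009 is a lead (<= 9x), 10^3.5x exactly is inactive
  ic50 <- c(0.001, 0.009, 0.0091, 1, 0.001 * 10^3.5, 50)
  ts <- tiny_ts(hy, to_pic50(ic50))
  part <- partition_by_activity(ts)
  expect_true(all(c(1, 2) %in% part$leads))
  expect_false(3 %in% part$leads)
  expect_true(5 %in% part$inactives) # boundary 10^3.5-fold is inclusive
  expect_true(6 %in% part$inactives)
  expect_true(4 %in% part$moderates) # 1 uM sits below the 3.16 uM boundary
  expect_setequal(c(part$leads, part$moderates, part$inactives), 1:6)

  # identical activities: everything is a lead
  ts2 <- tiny_ts(hy, rep(6, 5))
  part2 <- partition_by_activity(ts2)
  expect_length(part2$leads, 5)
  expect_length(part2$inactives, 0)
})

test_that("constructive phase recovers common features and respects caps", {
  hy <- make_pharmacophore(5, kinds = c("HBD", rep("HBic", 4)), seed = 5)
  pts <- points_on_centers(hy)
  leads <- lapply(1:3, function(i) pseudo_ligand(paste0("L", i), list(pts)))
  cands <- constructive_phase(leads, max_misses = 0)
  expect_gt(length(cands), 0)
  sigs <- vapply(cands, kind_signature, character(1))
  expect_true("HBD+4xHBic" %in% sigs)
  expect_true(all(vapply(cands, function(h) nrow(h$features), integer(1)) <= 5))
  # none of the leads carries an HBA, so no candidate may
  expect_false(any(grepl("HBA", sigs)))
  expect_error(constructive_phase(leads, max_features = 6), "exceed 5")
  expect_error(constructive_phase(leads[1]), "at least 2")
})

test_that("subtractive phase drops candidates mapped by most inactives", {
  hy <- make_pharmacophore(3, kinds = rep("HBic", 3), seed = 6)
  mapped <- pseudo_ligand("in1", list(points_on_centers(hy)))
  far <- points_on_centers(hy)
  far$kind <- "HBA" # kind-incompatible: cannot map under any rigid motion
  unmapped <- pseudo_ligand("in2", list(far))

  # mapped by every inactive: removed
  expect_length(subtractive_phase(list(hy), list(mapped, mapped)), 0)
  # mapped by none: retained
  expect_length(subtractive_phase(list(hy), list(unmapped, unmapped)), 1)
  # mapped by exactly half: retained (strict majority removes)
  expect_length(subtractive_phase(list(hy), list(mapped, unmapped)), 1)
  # empty inactives pass through
  expect_length(subtractive_phase(list(hy), list()), 1)
})

test_that("the activity line is recovered exactly on noiseless data", {
  hy <- make_pharmacophore(4, seed = 7)
  ts <- tiny_ts(hy, rep(5, 20), jitter = 0.45, seed = 7)
  fits <- fit_values(hy, ts$records)
  ts$pic50 <- setNames(0.9 * fits + 2, ts$ids)
  line <- fit_activity_line(hy, ts)
  expect_equal(line$slope, 0.9, tolerance = 1e-9)
  expect_equal(line$intercept, 2, tolerance = 1e-9)
  expect_equal(line$rmsd, 0, tolerance = 1e-9)

  # noisy recovery within +/- 0.1 of the true slope
  set.seed(77)
  hy2 <- make_pharmacophore(4, seed = 8)
  ts2 <- tiny_ts(hy2, rep(5, 60), jitter = 0.5, seed = 8)
  fits2 <- fit_values(hy2, ts2$records)
  ts2$pic50 <- setNames(0.9 * fits2 + 2 + rnorm(60, 0, 0.3), ts2$ids)
  line2 <- fit_activity_line(hy2, ts2)
  expect_lt(abs(line2$slope - 0.9), 0.1)

  # constant fits are degenerate
  ts3 <- tiny_ts(hy, rep(5, 20), jitter = 0, seed = 9)
  expect_error(fit_activity_line(hy, ts3), "zero variance")
})

test_that("error cost ignores residuals inside the uncertainty band", {
  expect_equal(error_cost(5.0, 5.4, uncertainty = 3), 0)
  expect_gt(error_cost(5.0, 6.0, uncertainty = 3), 0)
  expect_equal(error_cost(c(5, 6, 7), c(5, 6, 7)), 0)
  # band edge: |delta| = log10(3)
  expect_equal(error_cost(5, 5 + log10(3)), 0)
})

test_that("cost reports satisfy additivity and the residual identity", {
  cr <- cost_report(error_cost = 10, weight_cost = 2, config_cost = 3,
                    null_cost = 40)
  expect_equal(cr$total_cost, 15)
  expect_equal(cr$residual_cost, 25)
  expect_equal(cr$total_cost,
               cr$error_cost + cr$weight_cost + cr$config_cost)
  expect_equal(cr$residual_cost, cr$null_cost - cr$total_cost)
  expect_error(cost_report(-1, 0, 0, 10), ">= 0")
  expect_error(cost_report(1, 1, 1, 10, total_cost = 4), "total_cost")

  # total = null gives residual 0
  cr2 <- cost_report(5, 0, 0, 5)
  expect_equal(cr2$residual_cost, 0)
})

test_that("total_costs decomposes and handles weights and configs", {
  hy <- make_pharmacophore(4, seed = 10)
  ts <- tiny_ts(hy, rep(5, 20), jitter = 0.4, seed = 10)
  fits <- fit_values(hy, ts$records)
  ts$pic50 <- setNames(0.9 * fits + 2, ts$ids)
  cr <- total_costs(hy, ts, n_configs = 8)
  expect_equal(cr$weight_cost, 0) # unit weights
  expect_equal(cr$config_cost, 3) # log2(8)
  expect_equal(cr$total_cost, cr$error_cost + cr$weight_cost + cr$config_cost)
  expect_equal(cr$residual_cost, cr$null_cost - cr$total_cost)
  expect_error(total_costs(hy, ts, n_configs = 0), "n_configs")
})

test_that("optimisation is deterministic, sorted, and never hurts the best candidate", {
  truth <- make_pharmacophore(5, kinds = c("HBD", rep("HBic", 4)), seed = 12)
  ts <- make_training_set(truth, n = 20, seed = 12)
  part <- partition_by_activity(ts)
  leads <- ts$records[part$leads[order(ts$pic50[part$leads],
                                       decreasing = TRUE)]]
  cands <- constructive_phase(leads, min_features = 5)
  cands <- subtractive_phase(cands, ts$records[part$inactives])
  expect_gt(length(cands), 0)

  opts <- anneal_options(iterations = 30, n_anneal = 2)
  rk1 <- optimize_hypotheses(cands, ts, opts = opts, seed = 4)
  rk2 <- optimize_hypotheses(cands, ts, opts = opts, seed = 4)
  s1 <- attr(rk1, "summary")
  expect_identical(s1, attr(rk2, "summary"))
  expect_lte(length(rk1), 10)
  expect_false(is.unsorted(s1$total_cost))

  # the returned best is at least as good as every unoptimised candidate
  base_costs <- vapply(cands, function(h)
    total_costs(h, ts, n_configs = length(cands))$total_cost, numeric(1))
  expect_lte(s1$total_cost[1], min(base_costs) + 1e-9)

  expect_error(optimize_hypotheses(list(), ts), "no candidate")
})

test_that("estimate_activity applies the fit line with no-match at intercept", {
  hy <- make_pharmacophore(3, kinds = rep("HBic", 3), seed = 13)
  hy$fit_line <- c(slope = 1, intercept = 0)
  pts <- points_on_centers(hy)
  expect_equal(estimate_activity(hy, pseudo_ligand("a", list(pts))),
               3, tolerance = 1e-9)
  far <- pts
  far$kind <- "HBA"
  hy$fit_line <- c(slope = 2, intercept = 4.5)
  expect_equal(estimate_activity(hy, pseudo_ligand("b", list(far))), 4.5)
  hy$fit_line <- NULL
  expect_error(estimate_activity(hy, pseudo_ligand("a", list(pts))),
               "fit line")
})
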