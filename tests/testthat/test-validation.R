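test_that("enrichment statistics follow the count formulas", {
  em <- enrichment_metrics(enrichment_counts(D = 3606, A = 66, Ht = 75,
                                             Ha = 53))
  expect_equal(em$yield_pct, 100 * 53 / 75)
  expect_equal(em$ratio_pct, 100 * 53 / 66)
  expect_equal(em$enrichment, (53 / 75) / (66 / 3606))
  expect_equal(em$false_neg, 13)
  expect_equal(em$false_pos, 22)
  # identity E * Ht * A = Ha * D
  expect_equal(em$enrichment * 75 * 66, 53 * 3606, tolerance = 1e-9)

  # ideal retrieval and total miss
  ideal <- enrichment_metrics(enrichment_counts(3606, 66, 66, 66))
  expect_equal(ideal$gh, 1)
  expect_equal(ideal$enrichment, 3606 / 66)
  none <- enrichment_metrics(enrichment_counts(3606, 66, 75, 0))
  expect_equal(none$gh, 0)
  expect_equal(none$enrichment, 0)
  expect_equal(none$false_neg, 66)
  expect_equal(none$false_pos, 75)
})

test_that("invalid enrichment counts are rejected by name", {
  expect_error(enrichment_counts(100, 10, 5, 7), "Ha")
  expect_error(enrichment_counts(100, 0, 5, 0), "A >= 1")
  expect_error(enrichment_counts(100, 100, 5, 5), "A < D")
  expect_error(enrichment_counts(100, 10, 101, 5), "Ht")
  expect_error(enrichment_metrics(enrichment_counts(100, 10, 0, 0)),
               "undefined")
})

test_that("enrichment agrees with a label-counting oracle on random screens", {
  set.seed(31)
  for (i in 1:200) {
    D <- sample(20:80, 1)
    A <- sample(1:(D - 1), 1)
    labels <- c(rep("active", A), rep("decoy", D - A))
    ids <- paste0("m", seq_len(D))
    names(labels) <- ids
    hits <- sample(ids, sample(1:D, 1))
    Ha <- length(intersect(hits, ids[labels == "active"]))
    em <- enrichment_metrics(enrichment_counts(D, A, length(hits), Ha))
    # direct recount from the hit list
    expect_equal(em$yield_pct, 100 * mean(labels[hits] == "active"))
    expect_equal(em$false_pos, sum(labels[hits] == "decoy"))
    expect_equal(em$false_neg, A - sum(labels[hits] == "active"))
  }
})

test_that("GH is bounded in [0,1] and strictly increasing in Ha (small sweep)", {
  for (D in c(8, 15, 25)) {
    ok <- TRUE
    for (A in 1:(D - 1)) {
      for (Ht in 1:D) {
        Ha <- seq(max(0, Ht - (D - A)), min(A, Ht))
        gh <- gh_score(D, A, Ht, Ha)
        ok <- ok && all(gh >= -1e-12 & gh <= 1 + 1e-12)
        if (length(gh) > 1) ok <- ok && all(diff(gh) > 0)
      }
    }
    expect_true(ok)
  }
})

test_that("the Fischer scramble count matches the confidence level", {
  expect_identical(fischer_count(95), 19L)
  expect_identical(fischer_count(90), 9L)
  expect_identical(fischer_count(99), 99L)
  expect_error(fischer_count(93), "supported")
  expect_error(fischer_count(0), "between")
  expect_error(fischer_count(100), "between")
})

test_that("Fischer randomization produces the right report and detects signal", {
  truth <- make_pharmacophore(5, kinds = c("HBD", rep("HBic", 4)), seed = 41)
  ts <- make_training_set(truth, n = 20, seed = 41)
  fr <- fischer_randomization(ts, light_builder, confidence = 95, seed = 41)
  expect_equal(fr$n_scrambles, 19)
  expect_equal(nrow(fr$scrambled_stats), 19)
  expect_true(fr$significant)
  expect_gt(fr$original_stat[["train_r"]],
            max(fr$scrambled_stats$train_r, na.rm = TRUE))
})

test_that("test-set correlation matches its definition", {
  hy <- make_pharmacophore(4, seed = 51)
  hy$fit_line <- c(slope = 1, intercept = 0)
  set.seed(51)
  recs <- lapply(1:8, function(i) {
    pts <- points_on_centers(hy)
    pts[, c("x", "y", "z")] <- pts[, c("x", "y", "z")] +
      matrix(rnorm(nrow(pts) * 3, 0, 0.4), ncol = 3)
    pseudo_ligand(paste0("t", i), list(pts))
  })
  est <- vapply(recs, function(r) estimate_activity(hy, r), numeric(1))
  # estimates exactly equal observed
  expect_equal(test_set_correlation(hy, recs, est), 1, tolerance = 1e-9)
  # correlation is insensitive to a constant offset
  expect_equal(test_set_correlation(hy, recs, est + 2), 1, tolerance = 1e-9)
  expect_error(test_set_correlation(hy, recs[1:2], est[1:2]), "3")
  expect_error(test_set_correlation(hy, recs, rep(5, 8)), "variance")
})
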