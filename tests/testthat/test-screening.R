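test_that("the funnel filters, counts and ranks deterministically", {
  bench <- make_benchmark(60, 10, seed = 61)
  cfg <- screening_config(mode = "fast", seed = 61)
  res <- screen_library(bench$library, bench$truth, cfg)
  expect_identical(res$funnel$stage,
                   c("library", "parsed", "lipinski", "pharmacophore"))
  expect_false(is.unsorted(rev(res$funnel$count))) # non-increasing
  expect_equal(res$funnel$count[1], 60)
  # hits sorted by fit descending, ties by id
  expect_false(is.unsorted(rev(res$hits$fit)))
  # determinism
  res2 <- screen_library(bench$library, bench$truth, cfg)
  expect_identical(res$hits, res2$hits)
})

test_that("a rule-of-five violator is removed at the Lipinski stage", {
  hy <- make_pharmacophore(3, kinds = rep("HBic", 3), seed = 62)
  good <- pseudo_ligand("ok", list(points_on_centers(hy)),
                        descriptors = list(mw = 320, logp = 2.5,
                                           hbd_count = 1, hba_count = 4))
  heavy <- pseudo_ligand("heavy", list(points_on_centers(hy)),
                         descriptors = list(mw = 501, logp = 2.5,
                                            hbd_count = 1, hba_count = 4))
  res <- screen_library(list(good, heavy), hy,
                        screening_config(mode = "fast"))
  expect_equal(res$funnel$count, c(2, 2, 1, 1))
  expect_identical(res$hits$id, "ok")
})

test_that("the packaged score matrix loads losslessly", {
  path <- system.file("extdata", "table3_scores.csv",
                      package = "phorescreen")
  sm <- load_score_matrix(path)
  expect_equal(dim(sm$scores), c(9, 11))
  expect_equal(sm$scores["NSC35839", "LibDockScore"], 152.48)
  expect_equal(sm$scores["NSC659829", "Jain"], 2.75)
  # lossless round trip through disk
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = rownames(sm$scores), sm$scores,
                       check.names = FALSE), tmp, row.names = FALSE)
  expect_equal(load_score_matrix(tmp)$scores, sm$scores)

  # a blank cell is rejected with its location
  tab <- read.csv(path, check.names = FALSE)
  tab$Jain[2] <- NA
  write.csv(tab, tmp, row.names = FALSE)
  expect_error(load_score_matrix(tmp), "NSC80116, Jain")
})

test_that("consensus models are invariant to scorer scaling and ordering", {
  path <- system.file("extdata", "table3_scores.csv",
                      package = "phorescreen")
  sm <- load_score_matrix(path)
  known <- read.csv(system.file("extdata", "table3_pic50.csv",
                                package = "phorescreen"))
  pic50 <- setNames(known$pic50, known$id)
  model <- fit_consensus(sm, pic50)
  pred <- predict_consensus(model, sm)
  expect_true(all(is.finite(pred)))
  expect_length(pred, 9)

  # positive affine transform of one column leaves predictions unchanged
  sm2 <- sm
  sm2$scores[, "Jain"] <- 2 * sm2$scores[, "Jain"] + 10
  model2 <- fit_consensus(sm2, pic50)
  expect_equal(predict_consensus(model2, sm2), pred, tolerance = 1e-9)

  # permuting scorer columns leaves predictions unchanged
  sm3 <- sm
  sm3$scores <- sm3$scores[, rev(colnames(sm3$scores))]
  sm3$higher_is_better <- sm3$higher_is_better[rev(names(sm3$higher_is_better))]
  model3 <- fit_consensus(sm3, pic50)
  expect_equal(predict_consensus(model3, sm3)[names(pred)], pred,
               tolerance = 1e-9)

  expect_error(predict_consensus(model, structure(
    list(scores = sm$scores[, 1:3],
         higher_is_better = sm$higher_is_better[1:3]),
    class = "score_matrix")), "lacks")
})

test_that("consensus degenerates correctly for identical or single scorers", {
  X <- matrix(rnorm(18, 100, 10), 6, 3,
              dimnames = list(paste0("m", 1:6), c("s1", "s2", "s3")))
  X[, 2] <- X[, 1]
  X[, 3] <- X[, 1]
  sm <- structure(list(scores = X,
                       higher_is_better = setNames(rep(TRUE, 3),
                                                   colnames(X))),
                  class = "score_matrix")
  known <- setNames(rnorm(6, 7), rownames(X))
  model <- fit_consensus(sm, known)
  z <- (X[, 1] - mean(X[, 1])) / sd(X[, 1])
  # all columns identical: consensus equals that column's z-score
  expect_equal(phorescreen:::consensus_score(model, sm), z, tolerance = 1e-9)

  # a noiseless linear calibration is recovered exactly
  known2 <- 0.7 * z + 5
  model2 <- fit_consensus(sm, setNames(known2, rownames(X)))
  expect_equal(unname(predict_consensus(model2, sm)), unname(known2),
               tolerance = 1e-9)

  # single scorer: predictions are a monotone transform of the raw score
  sms <- structure(list(scores = X[, 1, drop = FALSE],
                        higher_is_better = c(s1 = TRUE)),
                   class = "score_matrix")
  m1 <- fit_consensus(sms, known)
  p1 <- predict_consensus(m1, sms)
  expect_identical(order(p1 * sign(m1$slope)), order(X[, 1]))

  # zero-variance scorer is dropped with a warning, or errors in strict mode
  Xz <- X
  Xz[, 2] <- 5
  smz <- structure(list(scores = Xz,
                        higher_is_better = setNames(rep(TRUE, 3),
                                                    colnames(Xz))),
                   class = "score_matrix")
  expect_warning(fit_consensus(smz, known), "zero-variance")
  expect_error(fit_consensus(smz, known, strict = TRUE), "zero-variance")
})
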