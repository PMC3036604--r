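test_that("feature perception matches the rule dictionary on known molecules", {
  met <- generate_conformers("CO", seed = 1, id = "methanol")
  fp <- perceive_features(met, 1)
  expect_equal(sort(fp$kind), c("HBA", "HBD"))

  ben <- generate_conformers("c1ccccc1", seed = 1, id = "benzene")
  fb <- perceive_features(ben, 1)
  expect_equal(fb$kind, "RingArom")
  ctr <- colMeans(ben$conformers[[1]])
  expect_equal(unlist(fb[1, c("x", "y", "z")], use.names = FALSE),
               unname(ctr), tolerance = 1e-8)

  # phenol by hand: O-H donor, O acceptor, one aromatic ring, no apolar
  # group (all carbons are aromatic)
  ph <- generate_conformers("Oc1ccccc1", seed = 1, id = "phenol")
  fph <- perceive_features(ph, 1)
  expect_equal(sort(fph$kind), c("HBA", "HBD", "RingArom"))
  # every feature cites its atoms
  expect_true(all(lengths(fph$atoms) >= 1))

  # thioanisole-like chain: apolar group centroid
  tol <- generate_conformers("Cc1ccccc1", seed = 1, id = "toluene")
  ftl <- perceive_features(tol, 1)
  expect_equal(sort(ftl$kind), c("HBic", "RingArom"))
})

test_that("weighted Kabsch recovers constructed rigid transforms", {
  set.seed(11)
  P <- matrix(rnorm(15), 5, 3)
  expect_equal(kabsch_align(P, P)$rmsd, 0, tolerance = 1e-10)
  expect_equal(kabsch_align(P, P)$rotation, diag(3), tolerance = 1e-8)

  for (i in 1:5) {
    R <- random_proper_rotation()
    t <- rnorm(3)
    Q <- sweep(P %*% t(R), 2, t, "+")
    a <- kabsch_align(P, Q, w = runif(5, 0.5, 2))
    expect_equal(a$rotation, R, tolerance = 1e-8)
    expect_equal(a$translation, t, tolerance = 1e-8)
    expect_lt(a$rmsd, 1e-8)
    expect_equal(det(a$rotation), 1, tolerance = 1e-8)
  }

  # mirror image of a chiral 4-point set cannot be superposed properly
  Pc <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  Qm <- Pc
  Qm[, 3] <- -Qm[, 3]
  expect_gt(kabsch_align(Pc, Qm)$rmsd, 0.1)

  expect_error(kabsch_align(P, P[1:3, ]), "identical dimensions")
  expect_error(kabsch_align(P, P, w = rep(0, 5)), "not all zero")
})

test_that("map_conformer scores exact and near matches per the fit formula", {
  hy <- make_pharmacophore(5, kinds = c("HBD", rep("HBic", 4)), seed = 3)
  pts <- points_on_centers(hy)
  m <- map_conformer(pts, hy)
  expect_equal(m$fit, 5, tolerance = 1e-9)
  expect_equal(m$rmsd, 0, tolerance = 1e-9)
  expect_equal(m$omitted_count, 0)

  # the fit equals sum w (1 - (d/tol)^2) under the returned alignment
  set.seed(4)
  pts2 <- pts
  pts2[, c("x", "y", "z")] <- pts2[, c("x", "y", "z")] +
    matrix(rnorm(15, 0, 0.3), 5, 3)
  m2 <- map_conformer(pts2, hy)
  C <- as.matrix(hy$features[, c("x", "y", "z")])
  Ct <- sweep(C %*% t(m2$rotation), 2, m2$translation, "+")
  Q <- as.matrix(pts2[m2$assignment, c("x", "y", "z")])
  d <- sqrt(rowSums((Ct - Q)^2))
  expect_equal(m2$fit,
               sum(hy$features$weight * (1 - (d / hy$features$tolerance)^2)),
               tolerance = 1e-9)
  expect_true(all(d <= hy$features$tolerance + 1e-9))

  # a point displaced beyond every tolerance: no match at max_omitted 0,
  # match with one omission and the displaced feature contributes nothing
  pts3 <- pts
  pts3$x[1] <- pts3$x[1] + 50
  expect_null(map_conformer(pts3, hy, max_omitted = 0))
  m3 <- map_conformer(pts3, hy, max_omitted = 1)
  expect_equal(m3$omitted_count, 1)
  expect_equal(m3$fit, 4, tolerance = 1e-6)
  expect_error(map_conformer(pts, hy, max_omitted = -1), "max_omitted")
})

test_that("fit is bounded, monotone and rigid-invariant", {
  set.seed(21)
  hy <- make_pharmacophore(4, seed = 21)
  for (i in 1:20) {
    pts <- points_on_centers(hy)
    pts[, c("x", "y", "z")] <- pts[, c("x", "y", "z")] +
      matrix(rnorm(nrow(pts) * 3, 0, runif(1, 0, 0.6)), ncol = 3)
    m <- map_conformer(pts, hy)
    if (is.null(m)) next
    expect_gte(m$fit, 0)
    expect_lte(m$fit, sum(hy$features$weight) + 1e-9)
    # rigid invariance
    mt <- map_conformer(transform_points(pts, random_proper_rotation(),
                                         rnorm(3, 0, 5)), hy)
    expect_equal(mt$fit, m$fit, tolerance = 1e-6)
  }
  # fit attains the weight total iff displacements vanish
  exact <- map_conformer(points_on_centers(hy), hy)
  expect_equal(exact$fit, sum(hy$features$weight), tolerance = 1e-9)
})

test_that("map_conformer agrees with the brute-force oracle on small cases", {
  set.seed(99)
  for (case in 1:6) {
    nf <- sample(2:3, 1)
    hy <- make_pharmacophore(nf, seed = 900 + case)
    npts <- sample(3:6, 1)
    pts <- points_on_centers(hy)[sample(nf, min(nf, npts), replace = FALSE), ]
    pts[, c("x", "y", "z")] <- pts[, c("x", "y", "z")] +
      matrix(rnorm(nrow(pts) * 3, 0, 0.4), ncol = 3)
    while (nrow(pts) < npts) {
      pts <- rbind(pts, data.frame(kind = sample(FEATURE_KINDS, 1),
                                   x = rnorm(1, 0, 3), y = rnorm(1, 0, 3),
                                   z = rnorm(1, 0, 3)))
    }
    pts <- transform_points(pts, random_proper_rotation(), rnorm(3, 0, 3))
    m <- best_fit(pts, hy, mode = "best", max_omitted = 0)
    o <- oracle_map_fit(pts, hy)
    if (is.null(o)) {
      # oracle found nothing feasible; the engine must not do worse than 0
      expect_true(is.null(m) || m$fit >= 0)
    } else {
      expect_false(is.null(m))
      expect_equal(m$fit, o, tolerance = 1e-3)
    }
  }
})

test_that("best_fit selects the best conformer and honours max_omitted 0", {
  hy <- make_pharmacophore(5, kinds = c("HBD", rep("HBic", 4)), seed = 8)
  good <- points_on_centers(hy)
  bad <- good
  bad$kind <- "HBA" # kind-incompatible conformer: nothing maps
  lig <- pseudo_ligand("two", list(bad, good))
  m <- best_fit(lig, hy, mode = "fast")
  expect_equal(m$conformer_index, 2)
  expect_equal(m$fit, 5, tolerance = 1e-9)

  single <- pseudo_ligand("one", list(good))
  expect_equal(best_fit(single, hy, mode = "fast")$fit,
               map_conformer(good, hy)$fit)

  # molecule lacking any HBD point cannot match the HBD+4xHBic query
  no_hbd <- good
  no_hbd$kind[no_hbd$kind == "HBD"] <- "HBA"
  expect_null(best_fit(pseudo_ligand("x", list(no_hbd)), hy,
                       max_omitted = 0))
  expect_error(best_fit(pseudo_ligand("x", list(good))[
    c("id")], hy), "conformer")
})

test_that("pharmacophore model files round-trip losslessly", {
  hy <- make_pharmacophore(5, seed = 14)
  hy$fit_line <- c(slope = 0.93, intercept = 4.21)
  hy$train_r <- 0.851
  path <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore(hy, path)
  back <- read_pharmacophore(path)
  expect_equal(back$features, hy$features, tolerance = 1e-12)
  expect_equal(back$fit_line, hy$fit_line)
  expect_equal(back$train_r, hy$train_r)

  # cap and invariant violations are rejected
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  obj$features <- c(obj$features, obj$features[1])[1:6]
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_pharmacophore(bad), "cap")

  obj$features <- obj$features[1:3]
  obj$features[[1]]$tolerance <- 0
  jsonlite::write_json(obj, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_pharmacophore(bad), "tolerance")

  expect_error(pharmacophore(rep("HBic", 6), matrix(rnorm(18), 6)), "at most 5")
})
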