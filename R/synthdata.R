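# Seeded generators for abstract "pseudo-ligands": feature-point sets with a
# planted pharmacophore, property-matched decoys and simulated activities.
# They let every pipeline stage be exercised without chemical structures or
# external databases; a small set of real SMILES covers the chemistry path
# separately.

#' Construct a pseudo-ligand
#'
#' A chemistry-free test carrier: one or more "conformers" given directly as
#' typed feature-point sets, plus an optional descriptor record for the
#' Lipinski stage.
#'
#' @param id Molecule identifier.
#' @param conformers List of feature-point data.frames (columns `kind`,
#'   `x`, `y`, `z`); at least one.
#' @param descriptors Optional list with `mw`, `logp`, `hbd_count`,
#'   `hba_count`.
#' @return An object of class `pseudo_ligand`.
#' @export
pseudo_ligand <- function(id, conformers, descriptors = NULL) {
  if (is.data.frame(conformers)) conformers <- list(conformers)
  if (length(conformers) < 1L) stop("a pseudo-ligand needs >= 1 conformer")
  for (cf in conformers) {
    if (!all(c("kind", "x", "y", "z") %in% names(cf)))
      stop("conformers need columns kind, x, y, z")
    if (any(!is.finite(as.matrix(cf[, c("x", "y", "z")]))))
      stop("non-finite feature coordinates")
  }
  structure(list(id = as.character(id), conformers = conformers,
                 descriptors = descriptors),
            class = "pseudo_ligand")
}

#' @export
print.pseudo_ligand <- function(x, ...) {
  cat(sprintf("Pseudo-ligand %s: %d conformer(s), %d feature point(s)\n",
              x$id, length(x$conformers), nrow(x$conformers[[1]])))
  invisible(x)
}

random_rotation <- function() {
  # uniform via QR of a Gaussian matrix, det +1
  M <- matrix(rnorm(9), 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rigid_jumble <- function(pos, translation_range = 5) {
  R <- random_rotation()
  t <- runif(3, -translation_range, translation_range)
  sweep(pos %*% t(R), 2, t, "+")
}

DEFAULT_KIND_WEIGHTS <- c(HBD = 0.20, HBA = 0.30, HBic = 0.25,
                          RingArom = 0.25)

sample_sphere <- function(n, radius) {
  out <- matrix(rnorm(3 * n), n, 3)
  out <- out / sqrt(rowSums(out^2))
  out * radius * runif(n)^(1 / 3)
}

drug_like_descriptors <- function() {
  list(mw = round(runif(1, 250, 480), 1),
       logp = round(runif(1, 0.5, 4.5), 2),
       hbd_count = sample(0:4, 1), hba_count = sample(2:8, 1))
}

#' Generate a random planted pharmacophore
#'
#' Feature centers are drawn uniformly in a sphere of radius `extent` under
#' a minimum pairwise separation of twice the tolerance (so feature spheres
#' do not overlap); kinds are sampled under `kind_weights` unless given
#' explicitly.
#'
#' @param n_features Number of features, 1 to 5.
#' @param kinds Optional explicit kind vector (length `n_features`).
#' @param kind_weights Sampling weights over [FEATURE_KINDS] (default
#'   hydrophobe-rich, mirroring typical ligand feature composition).
#' @param tolerance Feature tolerance, Angstrom (default 1.6).
#' @param extent Sphere radius for center placement, Angstrom (default 5,
#'   a typical small-molecule half-extent).
#' @param seed Integer seed.
#' @param max_tries Redraws allowed before giving up on the separation
#'   constraint.
#' @return A [pharmacophore()].
#' @export
make_pharmacophore <- function(n_features = 5, kinds = NULL,
                               kind_weights = DEFAULT_KIND_WEIGHTS,
                               tolerance = 1.6, extent = 5, seed = 1,
                               max_tries = 200) {
  if (n_features < 1 || n_features > 5)
    stop("n_features must lie in 1..5")
  if (!is.null(kinds) && length(kinds) != n_features)
    stop("kinds must have length n_features")
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      C <- sample_sphere(n_features, extent)
      if (n_features == 1 || min(stats::dist(C)) >= 2 * tolerance) {
        k <- kinds %||% sample(names(kind_weights), n_features,
                               replace = TRUE, prob = kind_weights)
        return(pharmacophore(k, C, tolerance = tolerance))
      }
    }
    stop("could not satisfy the center-separation constraint after ",
         max_tries, " tries; reduce n_features or enlarge extent")
  })
}

truth_extent <- function(truth) {
  max(sqrt(rowSums(feature_centers(truth)^2))) + 1.6
}

# One planted ligand: kept (possibly jittered) truth points + distractors,
# rigidly jumbled per conformer. The jittered truth content alone is kept as
# the "signal" attribute (first conformer), so callers can score the planted
# pharmacophoric content without distractor interference.
make_one_active <- function(truth, jitter_sd, n_distractors, n_conformers,
                            kind_weights, drop = 0) {
  C <- feature_centers(truth)
  kinds <- truth$features$kind
  keep <- seq_len(nrow(C))
  if (drop > 0) {
    n_keep <- max(0, nrow(C) - drop)
    keep <- if (n_keep == 0) integer(0) else sort(sample(keep, n_keep))
  }
  R <- truth_extent(truth)
  signal <- NULL
  confs <- lapply(seq_len(n_conformers), function(j) {
    pts <- C[keep, , drop = FALSE] +
      matrix(rnorm(3 * length(keep), 0, jitter_sd), ncol = 3)
    kk <- kinds[keep]
    if (j == 1)
      signal <<- data.frame(kind = kk, x = pts[, 1], y = pts[, 2],
                            z = pts[, 3], stringsAsFactors = FALSE)
    if (n_distractors > 0) {
      pts <- rbind(pts, sample_sphere(n_distractors, R))
      kk <- c(kk, sample(names(kind_weights), n_distractors, replace = TRUE,
                         prob = kind_weights))
    }
    pos <- rigid_jumble(pts)
    data.frame(kind = kk, x = pos[, 1], y = pos[, 2], z = pos[, 3],
               stringsAsFactors = FALSE)
  })
  attr(confs, "signal") <- signal
  confs
}

#' Generate planted actives
#'
#' Each active carries the truth's feature points under Gaussian positional
#' jitter, plus random distractor points, under a random rigid transform per
#' conformer. Draws failing the fit threshold against the truth are
#' resampled, so every returned active maps the planted model.
#'
#' @param truth The planted [pharmacophore()].
#' @param n Number of actives.
#' @param jitter_sd Positional noise, Angstrom (default 0.4).
#' @param n_distractors Extra unrelated feature points per conformer
#'   (default 7, giving ligands of about a dozen features).
#' @param n_conformers Conformers per ligand (default 3, emulating
#'   flexibility).
#' @param fit_threshold Minimum best-fit value against the truth (default
#'   60% of the maximum attainable fit).
#' @param kind_weights Distractor kind weights.
#' @param seed Integer seed.
#' @param max_tries Resampling attempts per active.
#' @param id_prefix Id prefix.
#' @return List of [pseudo_ligand()]s.
#' @export
make_actives <- function(truth, n, jitter_sd = 0.4, n_distractors = 7,
                         n_conformers = 3,
                         fit_threshold = 0.6 * sum(truth$features$weight),
                         kind_weights = DEFAULT_KIND_WEIGHTS, seed = 1,
                         max_tries = 60, id_prefix = "active") {
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (try in seq_len(max_tries)) {
        confs <- make_one_active(truth, jitter_sd, n_distractors,
                                 n_conformers, kind_weights)
        lig <- pseudo_ligand(sprintf("%s%04d", id_prefix, i), confs,
                             descriptors = drug_like_descriptors())
        m <- best_fit(lig, truth, mode = "fast", max_omitted = 0)
        if (!is.null(m) && m$fit >= fit_threshold) return(lig)
      }
      stop("could not reach the fit threshold after ", max_tries,
           " draws; reduce jitter_sd or the threshold")
    })
  })
}

#' Generate property-matched decoys
#'
#' Each decoy is built exactly like an active -- a private, randomly drawn
#' scaffold arrangement of well-separated feature points under the same
#' jitter, plus the same number of distractor points and conformers -- but
#' around its own arrangement rather than the planted truth (the
#' abstraction of physicochemically matched decoy sets: decoy molecules
#' have pharmacophoric content of their own, just not the active one). Any
#' draw that fully maps the truth is resampled, keeping the
#' decoy-versus-truth match rate at (essentially) zero, well under the 5%
#' contract.
#'
#' @param truth The planted [pharmacophore()].
#' @param n Number of decoys.
#' @param jitter_sd Positional noise applied to the decoy scaffold per
#'   conformer, Angstrom (default 0.4, as for actives).
#' @param n_distractors Distractor points per conformer (default 7).
#' @param n_conformers Conformers per decoy (default 3).
#' @param kind_weights Kind sampling weights for scaffolds and distractors;
#'   by default the truth's kinds are pooled with [DEFAULT_KIND_WEIGHTS] so
#'   decoys are kind-matched to the benchmark.
#' @param seed Integer seed.
#' @param max_tries Resampling attempts per decoy.
#' @param id_prefix Id prefix.
#' @return List of [pseudo_ligand()]s.
#' @export
make_decoys <- function(truth, n, jitter_sd = 0.4, n_distractors = 7,
                        n_conformers = 3, kind_weights = NULL, seed = 1,
                        max_tries = 60, id_prefix = "decoy") {
  if (n < 1) stop("n must be >= 1")
  if (is.null(kind_weights)) {
    kind_weights <- DEFAULT_KIND_WEIGHTS
    tk <- table(factor(truth$features$kind, levels = FEATURE_KINDS))
    kind_weights <- kind_weights + as.numeric(tk) / sum(tk)
    names(kind_weights) <- FEATURE_KINDS
  }
  nf <- nrow(truth$features)
  tol <- truth$features$tolerance[1]
  extent <- max(sqrt(rowSums(feature_centers(truth)^2)))
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      for (try in seq_len(max_tries)) {
        # private scaffold: same count/separation/extent statistics as the
        # truth, independent geometry and kinds
        scaffold <- NULL
        for (st in seq_len(50)) {
          C <- sample_sphere(nf, extent)
          if (nf == 1 || min(stats::dist(C)) >= 2 * tol) { scaffold <- C; break }
        }
        if (is.null(scaffold)) next
        sk <- sample(names(kind_weights), nf, replace = TRUE,
                     prob = kind_weights)
        own <- pharmacophore(sk, scaffold, tolerance = tol)
        confs <- make_one_active(own, jitter_sd, n_distractors,
                                 n_conformers, kind_weights)
        lig <- pseudo_ligand(sprintf("%s%05d", id_prefix, i),
                             unclass(confs),
                             descriptors = drug_like_descriptors())
        m <- best_fit(lig, truth, mode = "fast", max_omitted = 0)
        if (is.null(m)) return(lig)
      }
      stop("could not draw a non-mapping decoy after ", max_tries,
           " attempts")
    })
  })
}

#' Simulate activities linear in the fit against a planted model
#'
#' `pIC50 = slope * best_fit(ligand, truth) + intercept + N(0, noise_sd)`,
#' with partial mappings allowed (one omitted feature, matching the
#' activity-estimation convention of [fit_values()]) so the fit grades from
#' 0 to the feature-weight total. The defaults
#' (slope 0.9, intercept 4) place a 5-feature full match near pIC50 8.5 and
#' a non-binder near 4, spanning more than four orders of magnitude.
#'
#' @param truth The planted [pharmacophore()].
#' @param ligands List of [pseudo_ligand()]s.
#' @param slope,intercept Activity line (defaults 0.9 and 4).
#' @param noise_sd Activity noise, log units (default 0.3).
#' @param seed Integer seed.
#' @return Named numeric pIC50 vector.
#' @export
simulate_activities <- function(truth, ligands, slope = 0.9, intercept = 4,
                                noise_sd = 0.3, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  fits <- fit_values(truth, ligands)
  ids <- vapply(ligands, ligand_id, character(1))
  with_seed(seed,
            setNames(slope * fits + intercept + rnorm(length(fits), 0, noise_sd),
                     ids))
}

#' Generate a planted-model training set
#'
#' Builds `n` training pseudo-ligands at graded degradation -- positional
#' jitter drawn per ligand from `jitter_range`, and a cycle of
#' feature-knockout depths from full copies of the planted model down to
#' ligands with no planted content at all -- and simulates their activities
#' with [simulate_activities()]. The design guarantees the HypoGen-style
#' requirements (>= 16 ligands, activity span above four orders of
#' magnitude) and yields leads, moderates and inactives under the standard
#' partition.
#'
#' @param truth The planted [pharmacophore()].
#' @param n Training-set size (default 62).
#' @param noise_sd Activity noise, log units (default 0.3).
#' @param n_distractors Distractor points per ligand (default 7).
#' @param n_conformers Conformers per ligand (default 3).
#' @param jitter_range Range of per-ligand positional jitter, Angstrom
#'   (default 0.1 to 0.8).
#' @param uncertainty Activity uncertainty stored on the set (default 3).
#' @param slope,intercept Activity line for the simulation.
#' @param seed Integer seed.
#' @return A [training_set()].
#' @export
make_training_set <- function(truth, n = 62, noise_sd = 0.3,
                              n_distractors = 7, n_conformers = 3,
                              jitter_range = c(0.1, 0.8), uncertainty = 3,
                              slope = 0.9, intercept = 4, seed = 1) {
  nf <- nrow(truth$features)
  drops <- rep(c(0, 0, 1, 2, nf), length.out = n)
  records <- with_seed(child_seed(seed, 1), {
    jit <- runif(n, jitter_range[1], jitter_range[2])
    lapply(seq_len(n), function(i) {
      confs <- make_one_active(truth, jit[i], n_distractors,
                               n_conformers = n_conformers,
                               kind_weights = DEFAULT_KIND_WEIGHTS,
                               drop = drops[i])
      pseudo_ligand(sprintf("train%03d", i), confs,
                    descriptors = drug_like_descriptors())
    })
  })
  acts <- simulate_activities(truth, records, slope = slope,
                              intercept = intercept, noise_sd = noise_sd,
                              seed = child_seed(seed, 2))
  training_set(records, acts, uncertainty = uncertainty)
}

#' Generate a planted screening benchmark
#'
#' `A` planted actives plus `D - A` property-matched decoys in shuffled
#' order with retained labels, emulating a labelled actives/decoys
#' validation database.
#'
#' @param D Database size.
#' @param A Number of actives (`1 <= A < D`).
#' @param truth The planted [pharmacophore()]; default a fresh 5-feature
#'   model with the canonical one-donor/four-hydrophobe topology.
#' @param seed Integer seed.
#' @param ... Passed to [make_actives()] (jitter, distractors, threshold).
#' @return An object of class `planted_benchmark`: `library` (shuffled
#'   list of pseudo-ligands), `labels` (named `"active"`/`"decoy"`),
#'   `truth`, `params`.
#' @export
make_benchmark <- function(D, A, truth = NULL, seed = 1, ...) {
  if (A < 1 || A >= D) stop("need 1 <= A < D")
  if (is.null(truth))
    truth <- make_pharmacophore(5, kinds = c("HBD", rep("HBic", 4)),
                                seed = child_seed(seed, 10))
  actives <- make_actives(truth, A, seed = child_seed(seed, 11), ...)
  decoys <- make_decoys(truth, D - A, seed = child_seed(seed, 12))
  lib <- c(actives, decoys)
  labels <- setNames(c(rep("active", A), rep("decoy", D - A)),
                     vapply(lib, ligand_id, character(1)))
  ord <- with_seed(child_seed(seed, 13), sample(length(lib)))
  structure(list(library = lib[ord],
                 labels = labels[vapply(lib[ord], ligand_id, character(1))],
                 truth = truth,
                 params = list(D = D, A = A, seed = seed)),
            class = "planted_benchmark")
}

#' @export
print.planted_benchmark <- function(x, ...) {
  cat(sprintf("Planted benchmark: %d molecules (%d actives, %d decoys)\n",
              x$params$D, x$params$A, x$params$D - x$params$A))
  invisible(x)
}

#' Enrichment counts of a screen against benchmark labels
#'
#' @param bench A [make_benchmark()] result.
#' @param hits Hit table from [screen_library()] (or a character vector of
#'   hit ids).
#' @return An [enrichment_counts()] object.
#' @export
benchmark_counts <- function(bench, hits) {
  ids <- if (is.character(hits)) hits else hits$id
  enrichment_counts(D = length(bench$library),
                    A = sum(bench$labels == "active"),
                    Ht = length(ids),
                    Ha = sum(bench$labels[ids] == "active"))
}
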