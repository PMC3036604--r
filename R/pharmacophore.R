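#' Construct a pharmacophore hypothesis
#'
#' A pharmacophore is a set of at most five typed, weighted, toleranced
#' feature spheres in 3D space, optionally carrying a linear fit-to-activity
#' calibration (`fit_line`), a cost report and the training correlation.
#'
#' @param kinds Character vector of feature kinds (see [FEATURE_KINDS]).
#' @param centers Numeric matrix (one row per feature, columns x/y/z) of
#'   feature centers in Angstrom.
#' @param tolerance Feature sphere radius in Angstrom (default 1.6 A, a
#'   common ligand-based modeling default); recycled per feature. Must be
#'   strictly positive.
#' @param weight Non-negative feature weight (default 1); recycled.
#' @param fit_line Optional numeric vector `c(slope, intercept)` mapping a
#'   fit value to a predicted pIC50.
#' @param costs Optional [cost_report()].
#' @param train_r Optional training-set Pearson correlation.
#' @return An object of class `pharmacophore`.
#' @export
pharmacophore <- function(kinds, centers, tolerance = 1.6, weight = 1,
                          fit_line = NULL, costs = NULL, train_r = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3L) stop("centers must have 3 columns (x, y, z)")
  n <- length(kinds)
  if (nrow(centers) != n) stop("kinds and centers disagree in length")
  if (n > 5L) stop("a pharmacophore holds at most 5 features (got ", n, ")")
  kind_to_int(kinds) # validates
  tolerance <- rep_len(as.numeric(tolerance), n)
  weight <- rep_len(as.numeric(weight), n)
  if (any(!is.finite(centers))) stop("feature centers must be finite")
  if (any(tolerance <= 0)) stop("tolerance must be > 0")
  if (any(weight < 0)) stop("weight must be >= 0")
  features <- data.frame(kind = as.character(kinds),
                         x = centers[, 1], y = centers[, 2], z = centers[, 3],
                         tolerance = tolerance, weight = weight,
                         stringsAsFactors = FALSE)
  if (!is.null(fit_line)) {
    fit_line <- as.numeric(fit_line)
    if (length(fit_line) != 2L || any(!is.finite(fit_line)))
      stop("fit_line must be c(slope, intercept)")
    names(fit_line) <- c("slope", "intercept")
  }
  structure(list(features = features, fit_line = fit_line, costs = costs,
                 train_r = train_r),
            class = "pharmacophore")
}

#' @export
print.pharmacophore <- function(x, ...) {
  cat("Pharmacophore hypothesis:", nrow(x$features), "feature(s)\n")
  print(x$features, row.names = FALSE)
  if (!is.null(x$fit_line)) {
    cat(sprintf("fit line: pIC50 = %.4f * fit + %.4f\n",
                x$fit_line[["slope"]], x$fit_line[["intercept"]]))
  }
  if (!is.null(x$train_r)) cat(sprintf("training correlation R = %.3f\n", x$train_r))
  if (!is.null(x$costs)) print(x$costs)
  invisible(x)
}

feature_centers <- function(hypo) {
  as.matrix(hypo$features[, c("x", "y", "z")])
}

#' Kind multiset of a pharmacophore, e.g. "HBD+4xHBic"
#'
#' @param hypo A [pharmacophore()].
#' @return A single string naming each kind with its multiplicity, in the
#'   canonical kind order.
#' @export
kind_signature <- function(hypo) {
  tab <- table(factor(hypo$features$kind, levels = FEATURE_KINDS))
  tab <- tab[tab > 0]
  paste(ifelse(tab > 1, paste0(tab, "x", names(tab)), names(tab)),
        collapse = "+")
}

#' Read / write a pharmacophore model file
#'
#' Models are stored as JSON with schema
#' `{features: [{kind, center[3], tolerance, weight}], fit_line: {slope,
#' intercept}, costs, train_r}`. The round trip is lossless.
#'
#' @param path File path.
#' @return `read_pharmacophore()` returns a [pharmacophore()];
#'   `write_pharmacophore()` returns `path` invisibly.
#' @export
read_pharmacophore <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  if (is.null(obj$features)) stop("model file lacks a 'features' field")
  feats <- obj$features
  if (length(feats) > 5L) stop("model file declares ", length(feats),
                               " features; the cap is 5")
  kinds <- vapply(feats, function(f) {
    if (is.null(f$kind)) stop("feature lacks a 'kind' field")
    as.character(f$kind)
  }, character(1))
  centers <- t(vapply(feats, function(f) {
    ctr <- as.numeric(f$center)
    if (length(ctr) != 3L) stop("feature 'center' must have 3 coordinates")
    ctr
  }, numeric(3)))
  tolerance <- vapply(feats, function(f) as.numeric(f$tolerance %||% 1.6),
                      numeric(1))
  weight <- vapply(feats, function(f) as.numeric(f$weight %||% 1), numeric(1))
  fit_line <- if (!is.null(obj$fit_line))
    c(obj$fit_line$slope, obj$fit_line$intercept)
  costs <- if (!is.null(obj$costs)) do.call(cost_report, obj$costs)
  pharmacophore(kinds, centers, tolerance, weight, fit_line = fit_line,
                costs = costs, train_r = obj$train_r %||% NULL)
}

#' @param hypo A [pharmacophore()] to serialise.
#' @rdname read_pharmacophore
#' @export
write_pharmacophore <- function(hypo, path) {
  stopifnot(inherits(hypo, "pharmacophore"))
  f <- hypo$features
  obj <- list(
    features = lapply(seq_len(nrow(f)), function(i) list(
      kind = f$kind[i], center = c(f$x[i], f$y[i], f$z[i]),
      tolerance = f$tolerance[i], weight = f$weight[i])),
    fit_line = if (!is.null(hypo$fit_line))
      list(slope = hypo$fit_line[["slope"]],
           intercept = hypo$fit_line[["intercept"]]),
    costs = if (!is.null(hypo$costs)) unclass(hypo$costs),
    train_r = hypo$train_r)
  obj <- obj[!vapply(obj, is.null, logical(1))]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Weighted Kabsch superposition
#'
#' Finds the proper rotation (determinant +1) and translation minimising the
#' weighted sum of squared distances between corresponding points,
#' `sum_i w_i ||R p_i + t - q_i||^2`.
#'
#' @param P,Q Numeric matrices of matched points (rows), 3 columns each.
#' @param w Non-negative weights, not all zero (default equal).
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (weighted, Angstrom) and `distances` (per-point residual distances).
#' @export
kabsch_align <- function(P, Q, w = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("P and Q must have identical dimensions")
  if (nrow(P) < 1L || ncol(P) != 3L) stop("P and Q must be k x 3 with k >= 1")
  if (is.null(w)) w <- rep(1, nrow(P))
  w <- as.numeric(w)
  if (length(w) != nrow(P)) stop("w must have one weight per point")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be >= 0 and not all zero")
  res <- cpp_kabsch(P, Q, w)
  res$translation <- as.numeric(res$translation)
  res$distances <- as.numeric(res$distances)
  res
}

as_feature_points <- function(points) {
  if (is.data.frame(points)) {
    if (!all(c("kind", "x", "y", "z") %in% names(points)))
      stop("feature points need columns kind, x, y, z")
    list(pos = as.matrix(points[, c("x", "y", "z")]),
         kind = kind_to_int(points$kind), df = points)
  } else {
    stop("feature points must be a data.frame with kind, x, y, z")
  }
}

# Fit, rmsd and displacements of a fixed correspondence under a fixed
# rigid transform of the hypothesis onto the points.
transform_score <- function(hypo, points, assignment, rotation, translation) {
  keep <- which(!is.na(assignment))
  C <- feature_centers(hypo)[keep, , drop = FALSE]
  Q <- points$pos[assignment[keep], , drop = FALSE]
  w <- hypo$features$weight[keep]
  tol <- hypo$features$tolerance[keep]
  Ct <- C %*% t(rotation)
  Ct <- sweep(Ct, 2, translation, "+")
  d <- sqrt(rowSums((Ct - Q)^2))
  ratio <- d / tol
  list(fit = sum(w * pmax(0, 1 - ratio^2)),
       rmsd = sqrt(sum(w * d^2) / sum(w)),
       distances = d, feasible = all(ratio <= 1 + 1e-9))
}

rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Local rigid re-optimisation of an alignment: maximise the fit value over
# the 6 rigid parameters, with a quadratic penalty outside the tolerance
# spheres. Kabsch minimises weighted RMSD, which coincides with the
# fit-optimal transform only for equal tolerances, and its optimum can
# violate a tolerance another transform would satisfy; this polish recovers
# such cases ("best" search mode).
refine_alignment <- function(hypo, points, assignment, rotation, translation) {
  obj <- function(par) {
    R2 <- rotvec_to_matrix(par[1:3]) %*% rotation
    t2 <- translation + par[4:6]
    s <- transform_score(hypo, points, assignment, R2, t2)
    keep <- which(!is.na(assignment))
    tol <- hypo$features$tolerance[keep]
    over <- pmax(0, s$distances / tol - 1)
    -(s$fit - 100 * sum(over^2))
  }
  opt <- optim(rep(0, 6), obj, method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  R2 <- rotvec_to_matrix(opt$par[1:3]) %*% rotation
  t2 <- translation + opt$par[4:6]
  c(transform_score(hypo, points, assignment, R2, t2),
    list(rotation = R2, translation = t2))
}

new_mapping_result <- function(molecule_id, conformer_index, hypo, points,
                               assignment, fit, rmsd, rotation, translation) {
  keep <- !is.na(assignment)
  corr <- data.frame(feature = seq_along(assignment),
                     kind = hypo$features$kind,
                     point = assignment)
  structure(list(molecule_id = molecule_id,
                 conformer_index = conformer_index,
                 correspondence = corr,
                 assignment = assignment,
                 fit = fit, rmsd = rmsd,
                 omitted_count = sum(!keep),
                 rotation = rotation, translation = translation),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat(sprintf("Mapping: fit %.4f, rmsd %.4f A, %d omitted (molecule %s, conformer %s)\n",
              x$fit, x$rmsd, x$omitted_count,
              x$molecule_id %||% "?", x$conformer_index %||% "?"))
  invisible(x)
}

#' Map one conformer's feature points onto a pharmacophore
#'
#' Searches all kind-compatible injective correspondences between hypothesis
#' features and perceived feature points (allowing up to `max_omitted`
#' hypothesis features to be skipped), pruning by pairwise-distance
#' compatibility, aligning each correspondence by weighted Kabsch
#' superposition, and keeping only correspondences in which every mapped
#' displacement lies inside its feature's tolerance sphere. The returned
#' mapping maximises the fit value
#' `fit = sum_mapped w_f * (1 - (d_f / tol_f)^2)`;
#' ties are broken by lower rmsd, then lexicographic correspondence.
#'
#' @param points Feature points: a data.frame with columns `kind`, `x`, `y`,
#'   `z` (as produced by [perceive_features()]).
#' @param hypo A [pharmacophore()].
#' @param max_omitted Maximum number of hypothesis features that may be left
#'   unmapped (default 0: all features must map).
#' @param refine If `TRUE`, locally re-optimise the rigid alignment of the
#'   winning (and best near-miss) correspondence to maximise fit rather than
#'   minimise RMSD.
#' @return A `mapping_result` (fields `fit`, `rmsd`, `omitted_count`,
#'   `correspondence`, alignment), or `NULL` when no correspondence
#'   satisfies the tolerances (no match).
#' @export
map_conformer <- function(points, hypo, max_omitted = 0, refine = FALSE) {
  stopifnot(inherits(hypo, "pharmacophore"))
  if (nrow(hypo$features) == 0L) stop("hypothesis has no features")
  if (!is.numeric(max_omitted) || length(max_omitted) != 1L || max_omitted < 0)
    stop("max_omitted must be a single integer >= 0")
  fp <- as_feature_points(points)
  if (nrow(fp$pos) == 0L) return(NULL)
  res <- cpp_map_points(feature_centers(hypo), hypo$features$tolerance,
                        hypo$features$weight, kind_to_int(hypo$features$kind),
                        fp$pos, fp$kind, as.integer(max_omitted))
  out <- NULL
  if (isTRUE(res$found)) {
    out <- new_mapping_result(attr(points, "molecule_id"), NA_integer_,
                              hypo, fp, res$assignment, res$fit, res$rmsd,
                              res$rotation, as.numeric(res$translation))
  }
  if (refine) {
    # polish the winner
    if (!is.null(out)) {
      pol <- refine_alignment(hypo, fp, out$assignment, out$rotation,
                              out$translation)
      if (pol$feasible && pol$fit > out$fit + 1e-12) {
        out$fit <- pol$fit; out$rmsd <- pol$rmsd
        out$rotation <- pol$rotation; out$translation <- pol$translation
      }
    }
    # a near-miss correspondence may become feasible under a fit-optimal
    # (rather than RMSD-optimal) transform
    ia <- res$infeasible_assignment
    if (!all(is.na(ia))) {
      ka <- kabsch_align(feature_centers(hypo)[!is.na(ia), , drop = FALSE],
                         fp$pos[ia[!is.na(ia)], , drop = FALSE],
                         hypo$features$weight[!is.na(ia)])
      pol <- refine_alignment(hypo, fp, ia, ka$rotation, ka$translation)
      if (pol$feasible && (is.null(out) || pol$fit > out$fit + 1e-12)) {
        out <- new_mapping_result(attr(points, "molecule_id"), NA_integer_,
                                  hypo, fp, ia, pol$fit, pol$rmsd,
                                  pol$rotation, pol$translation)
      }
    }
  }
  out
}

conformer_points_list <- function(x) {
  if (inherits(x, "pseudo_ligand")) return(x$conformers)
  if (inherits(x, "conformer_set")) {
    return(lapply(seq_along(x$conformers), function(i)
      perceive_features(x, conformer = i)))
  }
  if (is.data.frame(x)) return(list(x))
  if (is.list(x) && all(vapply(x, is.data.frame, logical(1)))) return(x)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a conformer ensemble")
}

ligand_id <- function(x) {
  if (!is.null(x$id)) x$id
  else if (!is.null(x$molecule_id)) x$molecule_id
  else NA_character_
}

#' Best fit of a flexible molecule against a pharmacophore
#'
#' Evaluates every conformer of the ensemble with [map_conformer()] and
#' returns the maximum-fit mapping. In `"fast"` mode stored conformers are
#' scored as-is; `"best"` mode additionally re-optimises the rigid alignment
#' of each candidate mapping to maximise the fit value directly (the
#' Kabsch solve minimises weighted RMSD, which is only fit-optimal for equal
#' tolerances).
#'
#' @param x A conformer ensemble: a `pseudo_ligand`, a [generate_conformers()]
#'   result, a feature-point data.frame, or a list of such data.frames.
#' @param hypo A [pharmacophore()].
#' @param mode `"best"` (default, mirrors a best/flexible database search) or
#'   `"fast"`.
#' @param max_omitted Maximum omitted features (default 0). With 0, a
#'   molecule lacking any compatible point for some feature is no match.
#' @return The best `mapping_result` across conformers, or `NULL` (no match).
#' @export
best_fit <- function(x, hypo, mode = c("best", "fast"), max_omitted = 0) {
  mode <- match.arg(mode)
  confs <- conformer_points_list(x)
  if (length(confs) == 0L) stop("empty conformer ensemble")
  best <- NULL
  for (i in seq_along(confs)) {
    m <- map_conformer(confs[[i]], hypo, max_omitted = max_omitted,
                       refine = (mode == "best"))
    if (is.null(m)) next
    m$conformer_index <- i
    if (is.null(best) ||
        m$fit > best$fit + 1e-12 ||
        (abs(m$fit - best$fit) <= 1e-12 && m$rmsd < best$rmsd - 1e-12)) {
      best <- m
    }
  }
  if (!is.null(best)) best$molecule_id <- ligand_id(x) %||% best$molecule_id
  best
}
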