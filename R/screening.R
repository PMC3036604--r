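#' Virtual-screening configuration
#'
#' @param mode Pharmacophore search mode, `"best"` (alignment re-optimised
#'   per candidate mapping, as in a best/flexible database search) or
#'   `"fast"`.
#' @param max_omitted Maximum omitted features for a hit (default 0: a hit
#'   must satisfy every feature of the query).
#' @param fit_threshold Optional minimum fit value for a hit.
#' @param max_conformers,energy_window Conformer-generation settings used
#'   when the library provides structures rather than conformers
#'   (defaults 250 and 20 kcal/mol).
#' @param seed Integer seed (conformer generation).
#' @return A list of class `screening_config`.
#' @export
screening_config <- function(mode = c("best", "fast"), max_omitted = 0,
                             fit_threshold = NULL, max_conformers = 250,
                             energy_window = 20, seed = 1) {
  mode <- match.arg(mode)
  if (max_omitted < 0) stop("max_omitted must be >= 0")
  if (!is.null(fit_threshold) && !is.finite(fit_threshold))
    stop("fit_threshold must be finite")
  structure(list(mode = mode, max_omitted = as.integer(max_omitted),
                 fit_threshold = fit_threshold,
                 max_conformers = max_conformers,
                 energy_window = energy_window, seed = seed),
            class = "screening_config")
}

prepare_screen_record <- function(rec, cfg, k) {
  if (inherits(rec, "pseudo_ligand")) return(rec)
  if (inherits(rec, "conformer_set")) {
    return(pseudo_ligand(rec$molecule_id,
                         lapply(seq_along(rec$conformers), function(i)
                           perceive_features(rec, conformer = i))))
  }
  if (!is.null(rec$smiles)) {
    id <- rec$id %||% paste0("mol", k)
    desc <- compute_descriptors(rec$smiles, id = id)
    cs <- generate_conformers(rec$smiles, max_conformers = cfg$max_conformers,
                              energy_window = cfg$energy_window,
                              seed = child_seed(cfg$seed, k), id = id)
    return(pseudo_ligand(id,
                         lapply(seq_along(cs$conformers), function(i)
                           perceive_features(cs, conformer = i)),
                         descriptors = as.list(desc[1, c("mw", "logp",
                                                         "hbd_count",
                                                         "hba_count")])))
  }
  stop("unsupported library record")
}

#' Screen a molecule library through the pharmacophore funnel
#'
#' Runs the three-stage funnel: (1) Lipinski rule-of-five filter (molecules
#' without descriptor records pass through unfiltered), (2) conformer
#' preparation (records supplied as SMILES are embedded; pseudo-ligands carry
#' their conformers), (3) pharmacophore query with [best_fit()] under the
#' configured omitted-feature allowance. Hits are ranked by fit descending,
#' ties broken by id. Unparseable records are counted as rejected, never
#' silently dropped. Fully deterministic under `cfg$seed`.
#'
#' @param library List of records: `pseudo_ligand`s, `conformer_set`s, or
#'   lists with `id` and `smiles` fields (e.g. rows of
#'   [read_smiles_file()]).
#' @param hypo A [pharmacophore()] query.
#' @param cfg A [screening_config()].
#' @return A list with `hits` (data.frame `id`, `fit`, `conformer_index`,
#'   `rmsd`, `estimated_pic50`) and `funnel` (data.frame of stage names and
#'   surviving counts).
#' @export
screen_library <- function(library, hypo, cfg = screening_config()) {
  stopifnot(inherits(hypo, "pharmacophore"))
  if (length(library) == 0L) stop("empty screening library")
  if (is.data.frame(library))
    library <- lapply(seq_len(nrow(library)), function(i) as.list(library[i, ]))
  n0 <- length(library)
  prepared <- vector("list", n0)
  for (k in seq_len(n0)) {
    prepared[[k]] <- tryCatch(prepare_screen_record(library[[k]], cfg, k),
                              error = function(e) NULL)
  }
  ok <- !vapply(prepared, is.null, logical(1))
  prepared <- prepared[ok]
  # stage 1: Lipinski
  ro5_ok <- vapply(prepared, function(p) {
    if (is.null(p$descriptors)) return(TRUE)
    lipinski_filter(p$descriptors)$pass
  }, logical(1))
  survivors <- prepared[ro5_ok]
  # stage 2/3: conformers are present on every prepared record; query them
  hit_rows <- list()
  for (p in survivors) {
    m <- best_fit(p, hypo, mode = cfg$mode, max_omitted = cfg$max_omitted)
    if (is.null(m)) next
    if (!is.null(cfg$fit_threshold) && m$fit < cfg$fit_threshold) next
    est <- if (!is.null(hypo$fit_line))
      unname(hypo$fit_line[["slope"]] * m$fit + hypo$fit_line[["intercept"]])
    else NA_real_
    hit_rows[[length(hit_rows) + 1L]] <-
      data.frame(id = p$id, fit = m$fit, conformer_index = m$conformer_index,
                 rmsd = m$rmsd, estimated_pic50 = est,
                 stringsAsFactors = FALSE)
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(id = character(0), fit = numeric(0),
               conformer_index = integer(0), rmsd = numeric(0),
               estimated_pic50 = numeric(0))
  hits <- hits[order(-hits$fit, hits$id), , drop = FALSE]
  rownames(hits) <- NULL
  funnel <- data.frame(
    stage = c("library", "parsed", "lipinski", "pharmacophore"),
    count = c(n0, length(prepared), length(survivors), nrow(hits)))
  list(hits = hits, funnel = funnel)
}

# ---- consensus scoring --------------------------------------------------

#' Load a molecules-by-scoring-functions matrix
#'
#' Reads a CSV whose first column holds molecule ids and whose remaining
#' columns are named scoring functions. Every cell must parse to a finite
#' number; a missing cell is an error naming its row and column.
#'
#' @param path CSV path.
#' @param higher_is_better Orientation per scorer: `TRUE` (default) when a
#'   larger score is better; recycled, or a named logical vector.
#' @return An object of class `score_matrix`: fields `scores` (numeric
#'   matrix, molecules x scorers) and `higher_is_better`.
#' @export
load_score_matrix <- function(path, higher_is_better = TRUE) {
  tab <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("score matrix needs an id column plus scorers")
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicate molecule ids in score matrix")
  sc <- as.matrix(tab[, -1, drop = FALSE])
  mode(sc) <- "numeric"
  rownames(sc) <- ids
  if (any(is.na(sc))) {
    bad <- which(is.na(sc), arr.ind = TRUE)[1, ]
    stop("missing or non-numeric cell at (", ids[bad[1]], ", ",
         colnames(sc)[bad[2]], ")")
  }
  hib <- if (is.null(names(higher_is_better)))
    setNames(rep_len(higher_is_better, ncol(sc)), colnames(sc))
  else higher_is_better[colnames(sc)]
  structure(list(scores = sc, higher_is_better = hib),
            class = "score_matrix")
}

#' Fit a consensus activity model from a score matrix
#'
#' A transparent consensus: each scorer is z-normalised on the calibration
#' molecules (orientation-corrected so larger always means better), scorers
#' are averaged under the given weights, and the consensus score is
#' calibrated to pIC50 by least squares. Predictions are therefore invariant
#' to any positive affine rescaling of an individual scorer column.
#'
#' @param sm A [load_score_matrix()] result.
#' @param known Named numeric vector of calibration pIC50 values (names are
#'   molecule ids present in the matrix); at least 3.
#' @param weights Optional non-negative scorer weights (default equal);
#'   normalised to sum to 1.
#' @param strict Error (rather than warn and drop) on a zero-variance
#'   scorer.
#' @return An object of class `consensus_model`.
#' @export
fit_consensus <- function(sm, known, weights = NULL, strict = FALSE) {
  stopifnot(inherits(sm, "score_matrix"))
  ids <- intersect(names(known), rownames(sm$scores))
  if (length(ids) < 3L) stop("at least 3 calibration molecules required")
  X <- sm$scores[ids, , drop = FALSE]
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  if (is.null(weights)) weights <- rep(1, ncol(X))
  weights <- setNames(rep_len(as.numeric(weights), ncol(X)), colnames(X))
  if (any(weights < 0)) stop("weights must be >= 0")
  dead <- sg <= 0
  if (any(dead)) {
    if (strict) stop("zero-variance scorer(s): ",
                     paste(colnames(X)[dead], collapse = ", "))
    warning("dropping zero-variance scorer(s): ",
            paste(colnames(X)[dead], collapse = ", "))
    weights[dead] <- 0
    sg[dead] <- 1
  }
  if (sum(weights) <= 0) stop("no scorer left with positive weight")
  weights <- weights / sum(weights)
  model <- structure(list(scorers = colnames(X), mean = mu, sd = sg,
                          higher_is_better = sm$higher_is_better,
                          weights = weights, slope = NA_real_,
                          intercept = NA_real_),
                     class = "consensus_model")
  cons <- consensus_score(model, sm)[ids]
  fitl <- lm(known[ids] ~ cons)
  model$intercept <- unname(coef(fitl)[1])
  model$slope <- unname(coef(fitl)[2])
  model
}

consensus_score <- function(model, sm) {
  miss <- setdiff(model$scorers, colnames(sm$scores))
  if (length(miss)) stop("score matrix lacks scorer(s): ",
                         paste(miss, collapse = ", "))
  X <- sm$scores[, model$scorers, drop = FALSE]
  Z <- sweep(sweep(X, 2, model$mean), 2, model$sd, "/")
  flip <- !model$higher_is_better[model$scorers]
  Z[, flip] <- -Z[, flip]
  drop(Z %*% model$weights)
}

#' Predict pIC50 from a consensus model
#'
#' @param model A [fit_consensus()] result.
#' @param sm A [load_score_matrix()] result covering the model's scorers.
#' @return Named numeric vector of predicted pIC50 values.
#' @export
predict_consensus <- function(model, sm) {
  stopifnot(inherits(model, "consensus_model"))
  model$slope * consensus_score(model, sm) + model$intercept
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf("Consensus model over %d scorers; pIC50 = %.4f * z + %.4f\n",
              length(x$scorers), x$slope, x$intercept))
  invisible(x)
}
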