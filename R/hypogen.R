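#' Assemble a quantitative-model training set
#'
#' A training set couples activity-annotated ligands (each a conformer
#' ensemble of perceived feature points) with their pIC50 values and the
#' activity uncertainty. Following common HypoGen-style practice, it must
#' hold at least 16 molecules whose activities span at least four orders of
#' magnitude; both checks can be overridden for exploratory work.
#'
#' @param records List of ligands (`pseudo_ligand` objects, `conformer_set`s,
#'   or lists of feature-point data.frames), each with an `id`.
#' @param pic50 Numeric pIC50 per record (aligned with `records`, or named
#'   by id).
#' @param uncertainty Multiplicative activity uncertainty (default 3): an
#'   estimate within a factor of `uncertainty` of the measurement incurs no
#'   error cost. Must exceed 1.
#' @param override Skip the size / activity-span checks.
#' @return An object of class `training_set`.
#' @export
training_set <- function(records, pic50, uncertainty = 3, override = FALSE) {
  if (length(records) == 0L) stop("empty training set")
  ids <- vapply(records, function(r) as.character(ligand_id(r)), character(1))
  if (anyDuplicated(ids)) stop("duplicate ligand ids in training set")
  if (!is.null(names(pic50))) pic50 <- pic50[ids]
  pic50 <- as.numeric(pic50)
  if (length(pic50) != length(records) || anyNA(pic50))
    stop("pic50 must provide one finite value per record")
  if (uncertainty <= 1) stop("uncertainty must be > 1")
  if (!override) {
    if (length(records) < 16L)
      stop("training set has ", length(records),
           " records; at least 16 required (use override = TRUE to force)")
    if (diff(range(pic50)) < 4)
      stop("activity span is ", round(diff(range(pic50)), 2),
           " log units; at least 4 required (use override = TRUE to force)")
  }
  structure(list(records = records, ids = ids, pic50 = setNames(pic50, ids),
                 uncertainty = uncertainty),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("Training set: %d ligands, pIC50 %.2f-%.2f, uncertainty %g\n",
              length(x$records), min(x$pic50), max(x$pic50), x$uncertainty))
  invisible(x)
}

#' Partition a training set by activity
#'
#' Splits records into leads, moderately actives and inactives relative to
#' the most potent member: leads have IC50 within `uncertainty^2` of the
#' minimum IC50; inactives lie at least `10^3.5`-fold above it (boundary
#' inclusive); the rest are moderates. The partition is exhaustive and
#' disjoint.
#'
#' @param ts A [training_set()].
#' @return A list with integer index vectors `leads`, `moderates`,
#'   `inactives`.
#' @export
partition_by_activity <- function(ts) {
  stopifnot(inherits(ts, "training_set"))
  ic50 <- to_ic50(ts$pic50)
  mn <- min(ic50)
  leads <- which(ic50 <= ts$uncertainty^2 * mn + 1e-12 * mn)
  inact <- which(ic50 >= 10^3.5 * mn * (1 - 1e-12))
  inact <- setdiff(inact, leads)
  list(leads = leads,
       moderates = setdiff(seq_along(ic50), c(leads, inact)),
       inactives = inact)
}

# ---- fast scoring cache -------------------------------------------------

# Strip ligands down to matrices + integer kinds for the inner loops.
ligand_cache <- function(records) {
  lapply(records, function(r) {
    lapply(conformer_points_list(r), function(df) {
      list(pos = as.matrix(df[, c("x", "y", "z")]),
           kind = kind_to_int(df$kind))
    })
  })
}

hypo_arrays <- function(hypo) {
  list(centers = feature_centers(hypo), tol = hypo$features$tolerance,
       wt = hypo$features$weight, kind = kind_to_int(hypo$features$kind))
}

# Existence check: does any conformer of the cached ligand fully map?
maps_fully <- function(ha, conf_cache) {
  for (cf in conf_cache) {
    r <- cpp_map_points(ha$centers, ha$tol, ha$wt, ha$kind,
                        cf$pos, cf$kind, 0L, first_only = TRUE)
    if (isTRUE(r$found)) return(TRUE)
  }
  FALSE
}

# Best fit value per cached ligand (0 when nothing maps).
cached_fits <- function(ha, cache, max_omitted) {
  vapply(cache, function(confs) {
    best <- 0
    for (cf in confs) {
      r <- cpp_map_points(ha$centers, ha$tol, ha$wt, ha$kind,
                          cf$pos, cf$kind, max_omitted)
      if (isTRUE(r$found) && r$fit > best) best <- r$fit
    }
    best
  }, numeric(1))
}

# Omitted-feature allowance used when estimating activities: partial
# mappings grade weak binders (weakly active training compounds commonly
# map only a subset of a five-feature model), but a molecule missing more
# than one feature is treated as a non-binder (fit 0). Bounding the
# allowance keeps the estimate specific to the planted arrangement and the
# correspondence search small.
estimation_omitted <- function(hypo) min(1L, nrow(hypo$features) - 1L)

#' Fit values of a hypothesis over a set of ligands
#'
#' Activity estimation allows partial mappings (by default one feature may
#' be omitted), so weak binders receive graded low fit values rather than
#' an all-or-nothing score; molecules mapping fewer features score 0.
#'
#' @param hypo A [pharmacophore()].
#' @param records List of ligands.
#' @param max_omitted Omitted-feature allowance (default: one, capped at the
#'   feature count minus one).
#' @return Numeric fit value per ligand.
#' @export
fit_values <- function(hypo, records, max_omitted = estimation_omitted(hypo)) {
  cached_fits(hypo_arrays(hypo), ligand_cache(records), max_omitted)
}

#' Least-squares fit-to-activity line
#'
#' Regresses training pIC50 on hypothesis fit values. Ligands that map no
#' feature contribute fit 0 (dropping them would bias the line).
#'
#' @param hypo A [pharmacophore()].
#' @param ts A [training_set()].
#' @param fits Optional precomputed fit values.
#' @return List with `slope`, `intercept`, `fits`, `estimates`, `residuals`,
#'   `r` (Pearson correlation of estimate vs observed), `rmsd` (log units).
#' @export
fit_activity_line <- function(hypo, ts, fits = NULL) {
  if (is.null(fits)) fits <- fit_values(hypo, ts$records)
  if (sd(fits) < 1e-12)
    stop("degenerate hypothesis: zero variance in fit values")
  y <- as.numeric(ts$pic50)
  fit <- lm(y ~ fits)
  est <- as.numeric(fit$fitted.values)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       fits = fits, estimates = est, residuals = y - est,
       r = cor(fits, y), rmsd = sqrt(mean((y - est)^2)))
}

#' Error cost of activity estimates
#'
#' Residuals inside the multiplicative uncertainty band (a factor of
#' `uncertainty` either way, i.e. `log10(uncertainty)` log units) cost
#' nothing; beyond it the cost grows quadratically,
#' `k_e * sum(max(0, |obs - est| - log10(u))^2)` with
#' `k_e = 1 / (2 ln(2) sigma^2)` bits (`sigma` = 0.3 log units by default).
#'
#' @param observed,estimated pIC50 vectors.
#' @param uncertainty Multiplicative uncertainty (default 3).
#' @param sigma Reference activity noise, log units (default 0.3).
#' @return Error cost in bits.
#' @export
error_cost <- function(observed, estimated, uncertainty = 3, sigma = 0.3) {
  band <- log10(uncertainty)
  k_e <- 1 / (2 * log(2) * sigma^2)
  excess <- pmax(0, abs(observed - estimated) - band)
  k_e * sum(excess^2)
}

#' Construct a hypothesis cost report
#'
#' Total cost decomposes exactly as error + weight + configuration;
#' the residual cost is null minus total. The null cost is the error cost of
#' the constant mean-activity predictor; the fixed cost is the floor of a
#' zero-error hypothesis (its weight + configuration terms).
#'
#' @param error_cost,weight_cost,config_cost Cost components, bits.
#' @param null_cost Null-hypothesis cost, bits.
#' @param fixed_cost Cost floor, bits (default `weight_cost + config_cost`
#'   of an ideal-weight hypothesis, i.e. `config_cost`).
#' @param total_cost,residual_cost Optional; recomputed and checked when
#'   given.
#' @return An object of class `cost_report`.
#' @export
cost_report <- function(error_cost, weight_cost, config_cost, null_cost,
                        fixed_cost = config_cost, total_cost = NULL,
                        residual_cost = NULL) {
  comp <- c(error_cost = error_cost, weight_cost = weight_cost,
            config_cost = config_cost, null_cost = null_cost,
            fixed_cost = fixed_cost)
  if (any(comp < 0)) stop("cost components must be >= 0")
  total <- error_cost + weight_cost + config_cost
  if (!is.null(total_cost) && abs(total_cost - total) > 1e-6)
    stop("total_cost does not equal error + weight + config")
  residual <- null_cost - total
  if (!is.null(residual_cost) && abs(residual_cost - residual) > 1e-6)
    stop("residual_cost does not equal null - total")
  structure(list(error_cost = error_cost, weight_cost = weight_cost,
                 config_cost = config_cost, total_cost = total,
                 fixed_cost = fixed_cost, null_cost = null_cost,
                 residual_cost = residual),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat(sprintf(paste0("Costs (bits): error %.3f + weight %.3f + config %.3f",
                     " = total %.3f\n  null %.3f, fixed %.3f, residual %.3f\n"),
              x$error_cost, x$weight_cost, x$config_cost, x$total_cost,
              x$null_cost, x$fixed_cost, x$residual_cost))
  invisible(x)
}

#' Full cost decomposition of a hypothesis on a training set
#'
#' @param hypo A [pharmacophore()].
#' @param ts A [training_set()].
#' @param n_configs Number of candidate configurations explored (>= 1);
#'   its base-2 logarithm is the configuration cost.
#' @param k_w Weight-cost constant, bits per squared unit deviation from
#'   unit weight (default 1).
#' @param sigma Reference activity noise for [error_cost()] (default 0.3).
#' @param fits Optional precomputed fit values.
#' @return A [cost_report()].
#' @export
total_costs <- function(hypo, ts, n_configs, k_w = 1, sigma = 0.3,
                        fits = NULL) {
  if (n_configs < 1) stop("n_configs must be >= 1")
  line <- fit_activity_line(hypo, ts, fits = fits)
  e <- error_cost(ts$pic50, line$estimates, ts$uncertainty, sigma)
  w <- k_w * sum((hypo$features$weight - 1)^2)
  cfg <- log2(n_configs)
  null_e <- error_cost(ts$pic50, rep(mean(ts$pic50), length(ts$pic50)),
                       ts$uncertainty, sigma)
  cost_report(error_cost = e, weight_cost = w, config_cost = cfg,
              null_cost = null_e, fixed_cost = w * 0 + cfg)
}

# ---- constructive / subtractive phases ---------------------------------

dedup_signature <- function(hypo) {
  C <- feature_centers(hypo)
  k <- sort(hypo$features$kind)
  d <- if (nrow(C) > 1) sort(round(c(stats::dist(C)), 1)) else numeric(0)
  paste(c(k, format(d)), collapse = "|")
}

#' Constructive phase: common-feature candidate hypotheses from lead ligands
#'
#' Enumerates feature subsets of the reference (most active) lead, retaining
#' each subset as a candidate only if (almost) every other lead fully maps
#' it (maximum omitted features 0; up to `max_misses` leads may fail,
#' tolerating an experimental-noise outlier among the leads), then
#' deduplicates candidates by kind multiset and pairwise-distance signature.
#'
#' @param leads List of lead ligands, most active first; at least 2.
#' @param max_features Feature-count cap (default 5).
#' @param min_features Smallest candidate size enumerated (default 3).
#' @param kinds Allowed feature kinds (default all of [FEATURE_KINDS]).
#' @param tolerance Feature tolerance assigned to candidates, Angstrom.
#' @param max_misses Number of leads allowed to miss a candidate
#'   (default 1).
#' @return List of candidate [pharmacophore()]s (possibly empty).
#' @export
constructive_phase <- function(leads, max_features = 5, min_features = 3,
                               kinds = FEATURE_KINDS, tolerance = 1.6,
                               max_misses = 1) {
  if (length(leads) < 2L) stop("constructive phase needs at least 2 leads")
  if (max_features > 5L) stop("max_features cannot exceed 5")
  ref <- conformer_points_list(leads[[1]])[[1]]
  ref <- ref[ref$kind %in% kinds, , drop = FALSE]
  if (nrow(ref) == 0L) return(list())
  other_cache <- ligand_cache(leads[-1])
  np <- nrow(ref)
  ref_pos <- as.matrix(ref[, c("x", "y", "z")])
  ref_kind_int <- kind_to_int(ref$kind)
  # leads (by index into other_cache) that fail to map the subset fully;
  # NULL once more than max_misses fail
  subset_misses <- function(idx) {
    ha <- list(centers = ref_pos[idx, , drop = FALSE],
               tol = rep(tolerance, length(idx)),
               wt = rep(1, length(idx)),
               kind = ref_kind_int[idx])
    missed <- integer(0)
    for (j in seq_along(other_cache)) {
      if (!maps_fully(ha, other_cache[[j]])) {
        missed <- c(missed, j)
        if (length(missed) > max_misses) return(NULL)
      }
    }
    missed
  }
  # A lead failing a triple fails every superset, so cheap triple checks
  # prune the larger subsets: a candidate's missed leads include the union
  # of its triples' missed leads.
  miss3 <- list()
  if (np >= 3) {
    tri <- combn(np, 3)
    for (j in seq_len(ncol(tri))) {
      miss3[[paste(tri[, j], collapse = ",")]] <- subset_misses(tri[, j])
    }
  }
  triples_admit <- function(idx) {
    if (length(idx) <= 3) return(TRUE)
    sub <- combn(idx, 3)
    un <- integer(0)
    for (j in seq_len(ncol(sub))) {
      m <- miss3[[paste(sub[, j], collapse = ",")]]
      if (is.null(m)) return(FALSE)
      un <- union(un, m)
      if (length(un) > max_misses) return(FALSE)
    }
    TRUE
  }
  cands <- list()
  seen <- character(0)
  sizes <- seq(min(min_features, np), min(max_features, np))
  for (k in rev(sizes)) {
    subs <- combn(np, k)
    for (j in seq_len(ncol(subs))) {
      idx <- subs[, j]
      ok <- if (k == 3) !is.null(miss3[[paste(idx, collapse = ",")]])
            else triples_admit(idx) && !is.null(subset_misses(idx))
      if (!ok) next
      hy <- pharmacophore(ref$kind[idx],
                          scale(ref_pos[idx, , drop = FALSE], scale = FALSE),
                          tolerance = tolerance)
      sig <- dedup_signature(hy)
      if (sig %in% seen) next
      seen <- c(seen, sig)
      cands[[length(cands) + 1L]] <- hy
    }
  }
  cands
}

#' Subtractive phase: drop candidates that inactives also map
#'
#' A candidate fully mapped (no omitted features) by more than half of the
#' inactive ligands carries no discriminating information and is removed.
#'
#' @param candidates Candidate list from [constructive_phase()].
#' @param inactives List of inactive ligands (possibly empty).
#' @return The filtered candidate list.
#' @export
subtractive_phase <- function(candidates, inactives) {
  if (length(inactives) == 0L || length(candidates) == 0L) return(candidates)
  cache <- ligand_cache(inactives)
  keep <- vapply(candidates, function(hy) {
    ha <- hypo_arrays(hy)
    n_map <- sum(vapply(cache, function(cf_set) maps_fully(ha, cf_set),
                        logical(1)))
    n_map <= length(cache) / 2
  }, logical(1))
  candidates[keep]
}

# ---- simulated annealing ------------------------------------------------

#' Annealing options for hypothesis optimisation
#'
#' @param iterations Annealing steps per candidate (default 80).
#' @param sigma_center Gaussian step for feature centers, Angstrom
#'   (default 0.5).
#' @param sigma_tolerance Log-normal step for tolerances (default 0.1);
#'   tolerances are clamped to `[0.8, 3]` Angstrom.
#' @param sigma_weight Gaussian step for weights (default 0.1); weights are
#'   clamped to `[0.1, 3]`.
#' @param n_anneal Number of top-ranked candidates to anneal (default 5);
#'   0 skips annealing and ranks unoptimised candidates.
#' @param cooling Geometric cooling factor per step (default 0.97).
#' @param kind_swap Allow feature-kind swap moves (default `FALSE`).
#' @return A list of class `anneal_options`.
#' @export
anneal_options <- function(iterations = 80, sigma_center = 0.5,
                           sigma_tolerance = 0.1, sigma_weight = 0.1,
                           n_anneal = 5, cooling = 0.97, kind_swap = FALSE) {
  structure(list(iterations = iterations, sigma_center = sigma_center,
                 sigma_tolerance = sigma_tolerance,
                 sigma_weight = sigma_weight, n_anneal = n_anneal,
                 cooling = cooling, kind_swap = kind_swap),
            class = "anneal_options")
}

perturb_hypo <- function(hy, opts) {
  f <- hy$features
  i <- sample.int(nrow(f), 1)
  move <- sample(c("center", "tolerance", "weight",
                   if (opts$kind_swap) "kind"), 1)
  if (move == "center") {
    f[i, c("x", "y", "z")] <- f[i, c("x", "y", "z")] +
      rnorm(3, 0, opts$sigma_center)
  } else if (move == "tolerance") {
    f$tolerance[i] <- min(2.5, max(1, f$tolerance[i] *
                                     exp(rnorm(1, 0, opts$sigma_tolerance))))
  } else if (move == "weight") {
    f$weight[i] <- min(3, max(0.1, f$weight[i] + rnorm(1, 0, opts$sigma_weight)))
  } else {
    f$kind[i] <- sample(FEATURE_KINDS, 1)
  }
  hy$features <- f
  hy
}

anneal_candidate <- function(hy, ts, cache, n_configs, opts, k_w, sigma) {
  max_om <- estimation_omitted(hy)
  cost_of <- function(h) {
    fits <- cached_fits(hypo_arrays(h), cache, max_om)
    if (sd(fits) < 1e-12) return(list(cost = Inf, fits = fits))
    y <- as.numeric(ts$pic50)
    line <- lm(y ~ fits)
    e <- error_cost(y, as.numeric(line$fitted.values), ts$uncertainty, sigma)
    list(cost = e + k_w * sum((h$features$weight - 1)^2) + log2(n_configs),
         fits = fits)
  }
  cur <- hy
  cur_c <- cost_of(cur)$cost
  best <- cur
  best_c <- cur_c
  # starting temperature: accept ~half of uphill trial moves
  ups <- numeric(0)
  for (i in seq_len(min(30, opts$iterations))) {
    d <- cost_of(perturb_hypo(cur, opts))$cost - cur_c
    if (is.finite(d) && d > 0) ups <- c(ups, d)
  }
  T0 <- if (length(ups)) stats::median(ups) / log(2) else 1
  Tk <- max(T0, 1e-6)
  for (i in seq_len(opts$iterations)) {
    prop <- perturb_hypo(cur, opts)
    pc <- cost_of(prop)$cost
    d <- pc - cur_c
    if (is.finite(pc) && (d <= 0 || runif(1) < exp(-d / Tk))) {
      cur <- prop
      cur_c <- pc
      if (pc < best_c) { best <- prop; best_c <- pc }
    }
    Tk <- Tk * opts$cooling
  }
  best
}

finalize_hypothesis <- function(hy, ts, cache, n_configs, k_w, sigma) {
  fits <- cached_fits(hypo_arrays(hy), cache, estimation_omitted(hy))
  if (sd(fits) < 1e-12) return(NULL)
  line <- fit_activity_line(hy, ts, fits = fits)
  hy$fit_line <- c(slope = line$slope, intercept = line$intercept)
  hy$train_r <- line$r
  hy$costs <- total_costs(hy, ts, n_configs, k_w = k_w, sigma = sigma,
                          fits = fits)
  attr(hy, "rmsd") <- line$rmsd
  hy
}

#' Optimise candidate hypotheses by simulated annealing
#'
#' Ranks candidates by unoptimised total cost, anneals the best
#' `opts$n_anneal` of them (Gaussian perturbations of feature centers,
#' tolerances and weights; geometric cooling with the start temperature
#' chosen so about half of early uphill moves are accepted) and returns at
#' most the 10 lowest-total-cost hypotheses. Deterministic under `seed`.
#'
#' @param candidates Candidate [pharmacophore()]s (non-empty).
#' @param ts A [training_set()].
#' @param opts An [anneal_options()] list.
#' @param seed Integer seed.
#' @param k_w,sigma Cost-model constants (see [total_costs()]).
#' @param n_configs Configuration count for the configuration cost
#'   (default: number of candidates).
#' @param shortlist When more candidates than this survive, a cheaper
#'   pre-ranking (one omitted feature allowed) keeps only the best
#'   `shortlist` for the full partial-mapping cost evaluation (default 30).
#' @return An object of class `hypothesis_ranking`: a list of finalised
#'   hypotheses (costs, fit line, training R) sorted by total cost, with a
#'   summary data.frame attribute.
#' @export
optimize_hypotheses <- function(candidates, ts, opts = anneal_options(),
                                seed = 1, k_w = 1, sigma = 0.3,
                                n_configs = length(candidates),
                                shortlist = 30) {
  if (length(candidates) == 0L)
    stop("no candidate hypotheses survive; relax perception or partition settings")
  cache <- ligand_cache(ts$records)
  if (length(candidates) > shortlist) {
    pre <- vapply(candidates, function(h) {
      fits <- cached_fits(hypo_arrays(h), cache,
                          min(1L, nrow(h$features) - 1L))
      if (sd(fits) < 1e-12) return(Inf)
      y <- as.numeric(ts$pic50)
      e <- error_cost(y, as.numeric(lm(y ~ fits)$fitted.values),
                      ts$uncertainty, sigma)
      e + k_w * sum((h$features$weight - 1)^2)
    }, numeric(1))
    candidates <- candidates[order(pre)][seq_len(shortlist)]
  }
  base <- lapply(candidates, finalize_hypothesis, ts = ts, cache = cache,
                 n_configs = n_configs, k_w = k_w, sigma = sigma)
  ok <- !vapply(base, is.null, logical(1))
  base <- base[ok]
  if (length(base) == 0L)
    stop("all candidates are degenerate (constant fit values)")
  costs0 <- vapply(base, function(h) h$costs$total_cost, numeric(1))
  ord <- order(costs0)
  base <- base[ord]
  costs0 <- costs0[ord]
  out <- base
  if (opts$n_anneal > 0) {
    n_do <- min(opts$n_anneal, length(base))
    with_seed(seed, {
      for (i in seq_len(n_do)) {
        ann <- anneal_candidate(out[[i]], ts, cache, n_configs, opts,
                                k_w, sigma)
        fin <- finalize_hypothesis(ann, ts, cache, n_configs, k_w, sigma)
        # keep whichever of (annealed, initial) has the lower cost
        if (!is.null(fin) && fin$costs$total_cost <= out[[i]]$costs$total_cost)
          out[[i]] <- fin
      }
    })
  }
  costs <- vapply(out, function(h) h$costs$total_cost, numeric(1))
  ord <- order(costs)
  out <- out[ord][seq_len(min(10, length(out)))]
  summary <- data.frame(
    rank = seq_along(out),
    features = vapply(out, kind_signature, character(1)),
    rmsd = vapply(out, function(h) attr(h, "rmsd"), numeric(1)),
    train_r = vapply(out, function(h) h$train_r, numeric(1)),
    error_cost = vapply(out, function(h) h$costs$error_cost, numeric(1)),
    weight_cost = vapply(out, function(h) h$costs$weight_cost, numeric(1)),
    total_cost = vapply(out, function(h) h$costs$total_cost, numeric(1)),
    residual_cost = vapply(out, function(h) h$costs$residual_cost, numeric(1)))
  structure(out, summary = summary, class = "hypothesis_ranking")
}

#' @export
print.hypothesis_ranking <- function(x, ...) {
  cat("Hypothesis ranking (total cost ascending):\n")
  print(attr(x, "summary"), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Generate and rank quantitative pharmacophore hypotheses
#'
#' Runs the full pipeline: activity partition, constructive common-feature
#' enumeration over the leads, subtractive filtering against the inactives,
#' cost ranking and simulated-annealing optimisation.
#'
#' @inheritParams constructive_phase
#' @param ts A [training_set()].
#' @param anneal An [anneal_options()] list.
#' @param seed Integer seed.
#' @param k_w,sigma Cost-model constants.
#' @return A `hypothesis_ranking` (see [optimize_hypotheses()]).
#' @export
build_hypotheses <- function(ts, max_features = 5, min_features = 3,
                             tolerance = 1.6, anneal = anneal_options(),
                             seed = 1, k_w = 1, sigma = 0.3) {
  part <- partition_by_activity(ts)
  leads_idx <- part$leads[order(ts$pic50[part$leads], decreasing = TRUE)]
  if (length(leads_idx) < 2L)
    stop("fewer than 2 lead ligands; cannot run the constructive phase")
  leads_idx <- head(leads_idx, 12) # the most active leads drive the phase
  cands <- constructive_phase(ts$records[leads_idx],
                              max_features = max_features,
                              min_features = min_features,
                              tolerance = tolerance)
  cands <- subtractive_phase(cands, ts$records[part$inactives])
  if (length(cands) == 0L)
    stop("no common-feature candidates survive; relax perception settings ",
         "or lower min_features")
  optimize_hypotheses(cands, ts, opts = anneal, seed = seed, k_w = k_w,
                      sigma = sigma, n_configs = length(cands))
}

#' Predict activity of a molecule from a calibrated hypothesis
#'
#' Applies the hypothesis' linear fit-to-activity calibration to the
#' molecule's best fit value; a molecule mapping no feature receives the
#' intercept (fit 0).
#'
#' @param hypo A calibrated [pharmacophore()] (non-null `fit_line`).
#' @param ligand A conformer ensemble (see [best_fit()]).
#' @param mode Search mode passed to [best_fit()].
#' @return Predicted pIC50.
#' @export
estimate_activity <- function(hypo, ligand, mode = "fast") {
  if (is.null(hypo$fit_line)) stop("hypothesis has no fit line")
  m <- best_fit(ligand, hypo, mode = mode,
                max_omitted = estimation_omitted(hypo))
  fit <- if (is.null(m)) 0 else m$fit
  unname(hypo$fit_line[["slope"]] * fit + hypo$fit_line[["intercept"]])
}
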