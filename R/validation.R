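#' Retrieval counts of a virtual screen
#'
#' @param D Database size (total molecules screened).
#' @param A Actives in the database (`1 <= A < D`).
#' @param Ht Hits retrieved (`>= 0`).
#' @param Ha Active hits, i.e. true positives (`0 <= Ha <= min(A, Ht)`;
#'   also `Ht - Ha <= D - A`, since false positives cannot outnumber the
#'   inactives in the database).
#' @return An object of class `enrichment_counts`.
#' @export
enrichment_counts <- function(D, A, Ht, Ha) {
  vals <- c(D = D, A = A, Ht = Ht, Ha = Ha)
  if (any(vals != round(vals))) stop("counts must be integers")
  if (A < 1) stop("invariant violated: A >= 1")
  if (A >= D) stop("invariant violated: A < D")
  if (Ht > D) stop("invariant violated: Ht <= D")
  if (Ht < 0 || Ha < 0) stop("invariant violated: counts must be >= 0")
  if (Ha > min(A, Ht)) stop("invariant violated: Ha <= min(A, Ht)")
  if (Ht - Ha > D - A)
    stop("invariant violated: false positives (Ht - Ha) cannot exceed ",
         "the inactive count (D - A)")
  structure(as.list(vals), class = "enrichment_counts")
}

#' Guner-Henry score (vectorised)
#'
#' `GH = (Ha (3A + Ht) / (4 Ht A)) * (1 - (Ht - Ha) / (D - A))`: a composite
#' retrieval metric in `[0, 1]` combining the yield and recall of actives
#' with a false-positive penalty; 1 is the ideal screen.
#'
#' @param D,A,Ht,Ha Retrieval counts (vectors recycle).
#' @return GH score(s).
#' @export
gh_score <- function(D, A, Ht, Ha) {
  (Ha * (3 * A + Ht) / (4 * Ht * A)) * (1 - (Ht - Ha) / (D - A))
}

#' Enrichment statistics of a retrieval experiment
#'
#' Computes the percent yield of actives (`%Y = 100 Ha/Ht`), percent ratio
#' of actives retrieved (`%A = 100 Ha/A`), the enrichment factor
#' (`E = (Ha/Ht)/(A/D)`), the Guner-Henry score, and false negative /
#' positive counts.
#'
#' @param c An [enrichment_counts()] object (or the four counts given as
#'   `D`, `A`, `Ht`, `Ha`).
#' @return An object of class `enrichment_report` with fields `counts`,
#'   `yield_pct`, `ratio_pct`, `enrichment`, `gh`, `false_neg`, `false_pos`.
#' @export
enrichment_metrics <- function(c) {
  if (!inherits(c, "enrichment_counts")) {
    c <- do.call(enrichment_counts, as.list(c))
  }
  if (c$Ht < 1) stop("Ht = 0: percent yield is undefined")
  structure(list(counts = c,
                 yield_pct = 100 * c$Ha / c$Ht,
                 ratio_pct = 100 * c$Ha / c$A,
                 enrichment = (c$Ha / c$Ht) / (c$A / c$D),
                 gh = gh_score(c$D, c$A, c$Ht, c$Ha),
                 false_neg = c$A - c$Ha,
                 false_pos = c$Ht - c$Ha),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  c <- x$counts
  cat(sprintf("D %d, A %d, Ht %d, Ha %d\n", c$D, c$A, c$Ht, c$Ha))
  cat(sprintf("%%Y %.2f  %%A %.2f  E %.2f  GH %.4f  FN %d  FP %d\n",
              x$yield_pct, x$ratio_pct, x$enrichment, x$gh,
              x$false_neg, x$false_pos))
  invisible(x)
}

#' Number of scrambled datasets for a Fischer randomization level
#'
#' At confidence level `c` percent the test requires
#' `round(100 / (100 - c)) - 1` activity-scrambled datasets (19 at 95%).
#'
#' @param confidence Confidence level in percent; supported levels are
#'   90, 95, 98 and 99.
#' @return Integer scramble count.
#' @export
fischer_count <- function(confidence) {
  if (confidence <= 0 || confidence >= 100)
    stop("confidence must lie strictly between 0 and 100")
  q <- 100 / (100 - confidence)
  if (abs(q - round(q)) > 1e-9)
    stop("unsupported confidence level ", confidence,
         "; supported levels: 90, 95, 98, 99")
  as.integer(round(q)) - 1L
}

#' Fischer randomization test of a hypothesis-generation procedure
#'
#' Re-derives hypotheses on activity-scrambled copies of the training set
#' and declares the original significant only if its statistic strictly
#' beats every scramble. The comparison statistic is the training
#' correlation (higher is better) with total cost as tie-breaker, or the
#' total cost alone (lower is better).
#'
#' @param ts A [training_set()].
#' @param builder A function `function(ts, seed)` returning a list with
#'   elements `train_r` and `total_cost` (or `NULL` when no hypothesis can
#'   be built). Defaults to the top hypothesis of [build_hypotheses()].
#' @param confidence Confidence level in percent (default 95).
#' @param seed Integer seed controlling both the permutations and the
#'   builder's seeds.
#' @param statistic `"train_r"` (default) or `"total_cost"`.
#' @return An object of class `fischer_report`: `confidence`, `n_scrambles`,
#'   `original_stat`, `scrambled_stats`, `significant`.
#' @export
fischer_randomization <- function(ts, builder = NULL, confidence = 95,
                                  seed = 1,
                                  statistic = c("train_r", "total_cost")) {
  statistic <- match.arg(statistic)
  n_scr <- fischer_count(confidence)
  if (is.null(builder)) {
    builder <- function(ts, seed) {
      rk <- tryCatch(build_hypotheses(ts, seed = seed), error = function(e) NULL)
      if (is.null(rk)) return(NULL)
      list(train_r = rk[[1]]$train_r, total_cost = rk[[1]]$costs$total_cost)
    }
  }
  run_stat <- function(res) {
    if (is.null(res)) return(c(NA_real_, NA_real_))
    c(res$train_r %||% NA_real_, res$total_cost %||% NA_real_)
  }
  orig <- run_stat(builder(ts, child_seed(seed, 0)))
  scr <- matrix(NA_real_, n_scr, 2)
  for (k in seq_len(n_scr)) {
    perm <- with_seed(child_seed(seed, k), sample(length(ts$pic50)))
    ts_k <- ts
    ts_k$pic50 <- setNames(as.numeric(ts$pic50)[perm], ts$ids)
    scr[k, ] <- run_stat(builder(ts_k, child_seed(seed, 1000 + k)))
  }
  # is `b` strictly better than `a`? (failed builds are never better)
  beats <- function(b, a) {
    if (is.na(b[1]) && is.na(b[2])) return(FALSE)
    if (is.na(a[1]) && is.na(a[2])) return(TRUE)
    if (statistic == "total_cost") return(isTRUE(b[2] < a[2]))
    if (isTRUE(b[1] > a[1])) return(TRUE)
    if (isTRUE(b[1] == a[1])) return(isTRUE(b[2] < a[2]))
    FALSE
  }
  sig <- !any(vapply(seq_len(n_scr), function(k) beats(scr[k, ], orig) ||
                       (is.na(orig[1]) && is.na(orig[2])), logical(1)))
  structure(list(confidence = confidence, n_scrambles = n_scr,
                 statistic = statistic,
                 original_stat = setNames(orig, c("train_r", "total_cost")),
                 scrambled_stats = data.frame(train_r = scr[, 1],
                                              total_cost = scr[, 2]),
                 significant = sig),
            class = "fischer_report")
}

#' @export
print.fischer_report <- function(x, ...) {
  cat(sprintf("Fischer randomization: %d scrambles (%g%% confidence)\n",
              x$n_scrambles, x$confidence))
  cat(sprintf("original train_r %.3f / total cost %.3f; significant: %s\n",
              x$original_stat[1], x$original_stat[2], x$significant))
  invisible(x)
}

#' Squared correlation between estimated and observed test-set activity
#'
#' Scores every test ligand with [estimate_activity()] (no-match ligands
#' receive the intercept) and returns the squared Pearson correlation with
#' the observed pIC50.
#'
#' @param hypo A calibrated [pharmacophore()].
#' @param records List of test ligands (at least 3).
#' @param pic50 Observed pIC50 per record.
#' @return R squared.
#' @export
test_set_correlation <- function(hypo, records, pic50) {
  if (length(records) < 3L) stop("at least 3 test records required")
  if (length(pic50) != length(records)) stop("pic50 must match records")
  est <- vapply(records, function(r) estimate_activity(hypo, r), numeric(1))
  if (sd(est) < 1e-12 || sd(pic50) < 1e-12)
    stop("zero variance in estimates or observations")
  cor(est, pic50)^2
}
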