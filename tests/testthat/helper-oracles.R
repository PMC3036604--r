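# Independent oracles and small fixture builders. The brute-force mapper
# implements the fit definition from scratch (its own correspondence
# enumeration, rotation handling and scoring) so it shares no code path
# with the package's engine.

oracle_rotvec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# all injective kind-compatible assignments of hypothesis features to points
oracle_assignments <- function(kind_h, kind_p) {
  m <- length(kind_h)
  out <- list()
  rec <- function(pos, cur, used) {
    if (pos > m) {
      out[[length(out) + 1L]] <<- cur
      return()
    }
    for (p in seq_along(kind_p)) {
      if (!used[p] && kind_p[p] == kind_h[pos]) {
        used[p] <- TRUE
        rec(pos + 1, c(cur, p), used)
        used[p] <- FALSE
      }
    }
  }
  rec(1, integer(0), rep(FALSE, length(kind_p)))
  out
}

# Maximum-fit rigid placement for one correspondence: multistart rotation
# sampling plus Nelder-Mead polish of a feasibility-penalised fit.
oracle_best_transform_fit <- function(C, tol, w, Q, n_starts = 24) {
  score <- function(par) {
    R <- oracle_rotvec(par[1:3])
    Ct <- sweep(C %*% t(R), 2, par[4:6], "+")
    d <- sqrt(rowSums((Ct - Q)^2))
    r <- d / tol
    fit <- sum(w * pmax(0, 1 - r^2))
    pen <- 1000 * sum(pmax(0, r - 1)^2)
    c(fit - pen, all(r <= 1 + 1e-7), fit)
  }
  # coarse multistart, then restarted polish of the best basins
  starts <- lapply(seq_len(n_starts), function(i) {
    v <- rnorm(3)
    ang <- runif(1, 0, pi)
    c(v / sqrt(sum(v^2)) * ang, colMeans(Q) - colMeans(C))
  })
  coarse <- lapply(starts, function(st)
    optim(st, function(p) -score(p)[1], method = "Nelder-Mead",
          control = list(maxit = 150, reltol = 1e-8)))
  ord <- order(vapply(coarse, `[[`, numeric(1), "value"))
  best <- NULL
  for (k in head(ord, 4)) {
    par <- coarse[[k]]$par
    for (round in 1:2) { # restarting Nelder-Mead escapes stalls
      par <- optim(par, function(p) -score(p)[1], method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-12))$par
    }
    s <- score(par)
    if (s[2] > 0 && (is.null(best) || s[3] > best)) best <- s[3]
  }
  best
}

# Best feasible fit over all correspondences (max_omitted = 0); NULL when
# no feasible placement was found.
oracle_map_fit <- function(points, hypo, n_starts = 24) {
  C <- as.matrix(hypo$features[, c("x", "y", "z")])
  tol <- hypo$features$tolerance
  w <- hypo$features$weight
  Q_all <- as.matrix(points[, c("x", "y", "z")])
  asg <- oracle_assignments(hypo$features$kind, points$kind)
  best <- NULL
  for (a in asg) {
    f <- oracle_best_transform_fit(C, tol, w, Q_all[a, , drop = FALSE],
                                   n_starts)
    if (!is.null(f) && (is.null(best) || f > best)) best <- f
  }
  best
}

# feature points laid out exactly on a hypothesis' centers
points_on_centers <- function(hypo) {
  data.frame(kind = hypo$features$kind, x = hypo$features$x,
             y = hypo$features$y, z = hypo$features$z,
             stringsAsFactors = FALSE)
}

random_proper_rotation <- function() {
  M <- matrix(rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

transform_points <- function(df, R, t) {
  pos <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
  pos <- sweep(pos, 2, t, "+")
  df$x <- pos[, 1]; df$y <- pos[, 2]; df$z <- pos[, 3]
  df
}

# small activity table on disk for chemio tests
write_demo_activity_csv <- function(path, ids = c("m1", "m2", "m3"),
                                    smiles = c("CCO", "c1ccccc1O", "CCN"),
                                    ic50 = c(0.00106, 12, 80.5)) {
  write.csv(data.frame(id = ids, smiles = smiles, ic50_um = ic50),
            path, row.names = FALSE)
  path
}

# the light hypothesis builder used in Fischer randomization tests
light_builder <- function(ts, seed) {
  rk <- tryCatch(
    build_hypotheses(ts, min_features = 5,
                     anneal = anneal_options(n_anneal = 0), seed = seed),
    error = function(e) NULL)
  if (is.null(rk)) return(NULL)
  list(train_r = rk[[1]]$train_r, total_cost = rk[[1]]$costs$total_cost)
}
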