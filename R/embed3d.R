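# Deterministic lightweight 3D coordinate builder and seeded torsion-driving
# conformer search. Geometry is idealised (standard bond lengths, tetrahedral
# / trigonal angles, planar rings): adequate for toleranced pharmacophore
# work, not for force-field-grade structures.

COVALENT_RADIUS <- c(C = 0.77, N = 0.75, O = 0.73, S = 1.02, P = 1.06,
                     F = 0.71, Cl = 0.99, Br = 1.14, I = 1.33, B = 0.84,
                     Se = 1.17, Si = 1.11)
VDW_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, F = 1.47,
                Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Se = 1.90,
                Si = 2.10)

bond_length <- function(e1, e2, order, aromatic = FALSE) {
  r <- (COVALENT_RADIUS[e1] %|na|% 0.77) + (COVALENT_RADIUS[e2] %|na|% 0.77)
  if (aromatic) r * 0.93
  else if (order == 2) r * 0.87
  else if (order >= 3) r * 0.78
  else r
}

`%|na|%` <- function(a, b) if (is.na(a)) b else a

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0, 0) else v / n
}

any_perp <- function(v) {
  v <- normalize(v)
  ref <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  normalize(pracma_cross(v, ref))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

rotate_about_axis <- function(pts, origin, axis, angle) {
  R <- rotvec_to_matrix(normalize(axis) * angle)
  sweep(sweep(pts, 2, origin, "-") %*% t(R), 2, origin, "+")
}

# sp3 109.47 deg; sp2 (double bond or aromatic) 120; sp (triple/cumulated) 180
atom_angle <- function(mol, i) {
  b <- mol$bonds
  orders <- c(b$order[b$a1 == i], b$order[b$a2 == i])
  if (any(orders >= 3) || sum(orders >= 2) >= 2) pi
  else if (any(orders >= 2) || mol$atom_aromatic[i]) 120 * pi / 180
  else 109.47 * pi / 180
}

ring_cycle_order <- function(mol, ring) {
  # order ring atom indices along the cycle using adjacency
  k <- length(ring)
  out <- ring[1]
  prev <- -1L
  for (step in seq_len(k - 1)) {
    cur <- out[length(out)]
    nb <- intersect(mol$adjacency[[cur]], ring)
    nxt <- setdiff(nb, c(prev, out))
    if (length(nxt) == 0L) return(ring) # fallback: given order
    out <- c(out, nxt[1])
    prev <- cur
  }
  out
}

place_ring <- function(mol, coords, placed, ring, entry, parent) {
  cyc <- ring_cycle_order(mol, ring)
  # rotate cycle so it starts at the entry atom
  s <- which(cyc == entry)
  cyc <- c(cyc[s:length(cyc)], cyc[seq_len(s - 1)])
  k <- length(cyc)
  arom <- all(mol$atom_aromatic[cyc])
  side <- mean(vapply(seq_len(k), function(j) {
    a <- cyc[j]; b <- cyc[if (j == k) 1 else j + 1]
    bond_length(mol$elem[a], mol$elem[b], 1, aromatic = arom)
  }, numeric(1)))
  rc <- side / (2 * sin(pi / k))
  pos_a <- coords[entry, ]
  placed_in_ring <- cyc[placed[cyc]]
  if (length(placed_in_ring) >= 2) {
    # fused ring: anchor on a placed adjacent pair, keep the shared plane
    A <- NULL
    for (j in seq_len(k)) {
      a <- cyc[j]; b <- cyc[if (j == k) 1 else j + 1]
      if (placed[a] && placed[b]) { A <- a; B <- b; break }
    }
    if (is.null(A)) { A <- placed_in_ring[1]; B <- placed_in_ring[2] }
    mid <- (coords[A, ] + coords[B, ]) / 2
    ab <- normalize(coords[B, ] - coords[A, ])
    others <- setdiff(which(placed), cyc)
    nrm <- if (length(others) >= 1) {
      ref <- colMeans(coords[others, , drop = FALSE]) - mid
      normalize(pracma_cross(ab, pracma_cross(ref, ab)))
    } else any_perp(ab)
    apo <- rc * cos(pi / k)
    ctr1 <- mid + apo * nrm
    ctr2 <- mid - apo * nrm
    away <- if (length(others) >= 1) {
      o <- colMeans(coords[others, , drop = FALSE])
      if (sum((ctr1 - o)^2) >= sum((ctr2 - o)^2)) ctr1 else ctr2
    } else ctr1
    ctr <- away
    u <- normalize(coords[A, ] - ctr)
    n2 <- normalize(pracma_cross(u, normalize(coords[B, ] - ctr)))
    v <- pracma_cross(n2, u)
    sA <- which(cyc == A)
    cyc <- c(cyc[sA:length(cyc)], cyc[seq_len(sA - 1)])
    # choose sweep direction so the second atom matches B
    phi <- 2 * pi * (seq_len(k) - 1) / k
    cand1 <- ctr + rc * (cos(phi[2]) * u + sin(phi[2]) * v[])
    sgn <- if (sum((cand1 - coords[B, ])^2) < side^2 / 4) 1 else -1
    for (j in seq_len(k)) {
      at <- cyc[j]
      if (placed[at]) next
      coords[at, ] <- ctr + rc * (cos(sgn * phi[j]) * u + sin(sgn * phi[j]) * v)
      placed[at] <- TRUE
    }
  } else {
    # fresh ring entered through `entry`
    dirv <- if (!is.null(parent) && placed[parent]) {
      normalize(pos_a - coords[parent, ])
    } else c(1, 0, 0)
    nrm <- if (!is.null(parent) && placed[parent]) {
      gp <- setdiff(mol$adjacency[[parent]], entry)
      gp <- gp[placed[gp]]
      if (length(gp) >= 1) {
        w <- normalize(coords[gp[1], ] - coords[parent, ])
        normalize(pracma_cross(dirv, w))
      } else any_perp(dirv)
    } else any_perp(dirv)
    ctr <- pos_a + rc * dirv
    u <- normalize(pos_a - ctr)
    v <- pracma_cross(nrm, u)
    phi <- 2 * pi * (seq_len(k) - 1) / k
    for (j in seq_len(k)) {
      at <- cyc[j]
      if (placed[at]) next
      coords[at, ] <- ctr + rc * (cos(phi[j]) * u + sin(phi[j]) * v)
      placed[at] <- TRUE
    }
  }
  list(coords = coords, placed = placed)
}

place_chain_atom <- function(mol, coords, placed, a, p) {
  L <- {
    b <- mol$bonds
    hit <- (b$a1 == a & b$a2 == p) | (b$a1 == p & b$a2 == a)
    o <- if (any(hit)) b$order[which(hit)[1]] else 1
    bond_length(mol$elem[a], mol$elem[p], o,
                aromatic = mol$atom_aromatic[a] && mol$atom_aromatic[p])
  }
  nb_p <- mol$adjacency[[p]]
  nb_placed <- nb_p[placed[nb_p] & nb_p != a]
  pos_p <- coords[p, ]
  if (length(nb_placed) == 0L) {
    others <- setdiff(which(placed), p)
    dirv <- if (length(others)) normalize(pos_p - colMeans(coords[others, , drop = FALSE]))
            else c(1, 0, 0)
    coords[a, ] <- pos_p + L * dirv
  } else if (length(nb_placed) >= 2L) {
    dirs <- t(apply(coords[nb_placed, , drop = FALSE], 1,
                    function(q) normalize(q - pos_p)))
    dirv <- -colSums(dirs)
    if (sqrt(sum(dirv^2)) < 1e-6) dirv <- any_perp(dirs[1, ])
    coords[a, ] <- pos_p + L * normalize(dirv)
  } else {
    g <- nb_placed[1]
    bvec <- normalize(coords[g, ] - pos_p)
    theta <- atom_angle(mol, p)
    # torsion reference
    nb_g <- setdiff(mol$adjacency[[g]], p)
    nb_g <- nb_g[placed[nb_g]]
    perp0 <- if (length(nb_g) >= 1) {
      w <- coords[nb_g[1], ] - coords[g, ]
      pp <- w - sum(w * bvec) * bvec
      if (sqrt(sum(pp^2)) < 1e-6) any_perp(bvec) else normalize(pp)
    } else any_perp(bvec)
    phis <- c(180, 60, -60, 120, -120, 0) * pi / 180
    best <- NULL
    best_mind <- -Inf
    for (phi in phis) {
      perp <- rotate_about_axis(matrix(perp0, 1), c(0, 0, 0), bvec, phi)[1, ]
      dirv <- cos(theta) * bvec + sin(theta) * perp
      cand <- pos_p + L * normalize(dirv)
      others <- setdiff(which(placed), c(p))
      mind <- if (length(others)) min(sqrt(rowSums(sweep(coords[others, , drop = FALSE], 2, cand, "-")^2)))
              else Inf
      if (mind >= 1.2) { best <- cand; break }
      if (mind > best_mind) { best_mind <- mind; best <- cand }
    }
    coords[a, ] <- best
  }
  coords
}

# Deterministic idealised 3D coordinates for a molecule graph.
embed_molecule <- function(mol) {
  n <- length(mol$elem)
  coords <- matrix(0, n, 3)
  placed <- rep(FALSE, n)
  in_ring <- rep(FALSE, n)
  for (r in mol$rings) in_ring[r] <- TRUE
  start <- 1L
  queue <- c(start)
  parent <- rep(NA_integer_, n)
  if (in_ring[start]) {
    ring <- mol$rings[[which(vapply(mol$rings, function(r) start %in% r,
                                    logical(1)))[1]]]
    coords[start, ] <- c(0, 0, 0)
    placed[start] <- TRUE
    pr <- place_ring(mol, coords, placed, ring, start, NULL)
    coords <- pr$coords; placed <- pr$placed
  } else {
    placed[start] <- TRUE
  }
  visited <- rep(FALSE, n)
  visited[start] <- TRUE
  while (length(queue)) {
    p <- queue[1]
    queue <- queue[-1]
    for (a in mol$adjacency[[p]]) {
      if (!visited[a]) {
        visited[a] <- TRUE
        parent[a] <- p
        queue <- c(queue, a)
      }
      if (placed[a]) next
      if (in_ring[a]) {
        rings_a <- mol$rings[vapply(mol$rings, function(r) a %in% r,
                                    logical(1))]
        coords <- place_chain_atom(mol, coords, placed, a, p)
        placed[a] <- TRUE
        for (ring in rings_a) {
          if (!all(placed[ring])) {
            pr <- place_ring(mol, coords, placed, ring, a, p)
            coords <- pr$coords; placed <- pr$placed
          }
        }
      } else {
        coords <- place_chain_atom(mol, coords, placed, a, p)
        placed[a] <- TRUE
      }
    }
  }
  # disconnected fragments (salts etc.): offset along x
  while (any(!placed)) {
    f <- which(!placed)[1]
    coords[f, ] <- c(max(coords[placed, 1]) + 4, 0, 0)
    placed[f] <- TRUE
    # grow its fragment
    queue <- c(f)
    visited[f] <- TRUE
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (a in mol$adjacency[[p]]) {
        if (placed[a]) next
        coords <- place_chain_atom(mol, coords, placed, a, p)
        placed[a] <- TRUE
        queue <- c(queue, a)
      }
    }
  }
  rownames(coords) <- paste0(mol$elem, "_", seq_len(n))
  coords
}

graph_distances <- function(mol) {
  n <- length(mol$elem)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    queue <- s
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (a in mol$adjacency[[cur]]) {
        if (D[s, a] > D[s, cur] + 1) {
          D[s, a] <- D[s, cur] + 1
          queue <- c(queue, a)
        }
      }
    }
  }
  D
}

# Simple Lennard-Jones-style steric energy (kcal/mol) over atom pairs at
# graph distance >= 3; used only to rank and window conformers.
steric_energy <- function(coords, mol, gd, eps = 0.1) {
  n <- nrow(coords)
  if (n < 4) return(0)
  e <- 0
  rv <- VDW_RADIUS[mol$elem]
  rv[is.na(rv)] <- 1.7
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (gd[i, j] < 3) next
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      r0 <- 0.9 * (rv[i] + rv[j])
      x <- (r0 / max(r, 0.3))^6
      e <- e + eps * (x^2 - 2 * x)
    }
  }
  e
}

rotatable_bonds <- function(mol) {
  b <- mol$bonds
  in_ring <- rep(FALSE, length(mol$elem))
  for (r in mol$rings) in_ring[r] <- TRUE
  keep <- b$order == 1 &
    mol$degree[b$a1] >= 2 & mol$degree[b$a2] >= 2 &
    !(vapply(seq_len(nrow(b)), function(k) {
      any(vapply(mol$rings, function(r) b$a1[k] %in% r && b$a2[k] %in% r,
                 logical(1)))
    }, logical(1)))
  b[keep, , drop = FALSE]
}

# atoms on the a2 side of bond (a1, a2), excluding a1's side
bond_side <- function(mol, a1, a2) {
  n <- length(mol$elem)
  seen <- rep(FALSE, n)
  seen[a2] <- TRUE
  queue <- a2
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (a in mol$adjacency[[cur]]) {
      if (a == a1 && cur == a2) next
      if (!seen[a] && a != a1) {
        seen[a] <- TRUE
        queue <- c(queue, a)
      }
    }
  }
  which(seen)
}

apply_torsions <- function(coords, mol, rb, sides, angles) {
  for (k in seq_len(nrow(rb))) {
    if (abs(angles[k]) < 1e-12) next
    axis <- coords[rb$a2[k], ] - coords[rb$a1[k], ]
    coords[sides[[k]], ] <- rotate_about_axis(
      coords[sides[[k]], , drop = FALSE], coords[rb$a1[k], ], axis, angles[k])
  }
  coords
}

heavy_rmsd <- function(A, B) {
  kabsch_align(A, B)$rmsd
}

#' Generate a conformer ensemble
#'
#' Builds deterministic idealised 3D coordinates for the molecule and
#' explores torsional space around rotatable bonds: a systematic grid over
#' staggered rotamers when small enough, otherwise seeded random torsion
#' draws. Conformers are ranked by a simple steric (Lennard-Jones-style)
#' energy, kept within `energy_window` kcal/mol of the minimum, deduplicated
#' at `dedup_rmsd` (heavy-atom RMSD after superposition) and capped at
#' `max_conformers`. Identical structure, settings and seed give bit-identical
#' ensembles.
#'
#' @param m A `phmol` (see [parse_structure()]) or a SMILES string.
#' @param max_conformers Ensemble size cap (default 250).
#' @param energy_window Maximum relative energy retained, kcal/mol
#'   (default 20).
#' @param seed Integer seed for the torsion draws.
#' @param dedup_rmsd Duplicate-geometry threshold in Angstrom (default 0.5).
#' @param id Molecule id when `m` is a SMILES string.
#' @return An object of class `conformer_set`: fields `molecule_id`, `mol`,
#'   `conformers` (list of heavy-atom coordinate matrices, Angstrom),
#'   `rel_energies` (kcal/mol above the minimum member), `seed`, `settings`.
#' @export
generate_conformers <- function(m, max_conformers = 250, energy_window = 20,
                                seed = 1, dedup_rmsd = 0.5, id = "mol") {
  if (max_conformers < 1) stop("max_conformers must be >= 1")
  if (energy_window <= 0) stop("energy_window must be > 0")
  mol <- if (inherits(m, "phmol")) m else parse_structure(m, id = id)
  base <- tryCatch(embed_molecule(mol),
                   error = function(e) stop("3D embedding failed for '",
                                            mol$id, "': ",
                                            conditionMessage(e),
                                            call. = FALSE))
  gd <- graph_distances(mol)
  rb <- rotatable_bonds(mol)
  cands <- list()
  energies <- numeric(0)
  if (nrow(rb) == 0L) {
    cands <- list(base)
    energies <- 0
  } else {
    sides <- lapply(seq_len(nrow(rb)), function(k)
      bond_side(mol, rb$a1[k], rb$a2[k]))
    stagger <- c(0, 2 * pi / 3, -2 * pi / 3)
    n_grid <- 3^nrow(rb)
    with_seed(seed, {
      if (n_grid <= 3 * max_conformers) {
        grid <- as.matrix(expand.grid(rep(list(stagger), nrow(rb))))
        angle_sets <- lapply(seq_len(nrow(grid)), function(i) grid[i, ])
      } else {
        angle_sets <- lapply(seq_len(3 * max_conformers), function(i)
          sample(stagger, nrow(rb), replace = TRUE) +
            rnorm(nrow(rb), 0, 10 * pi / 180))
      }
      for (ang in angle_sets) {
        cc <- apply_torsions(base, mol, rb, sides, ang)
        cands[[length(cands) + 1L]] <- cc
        energies <- c(energies, steric_energy(cc, mol, gd))
      }
    })
  }
  ord <- order(energies, seq_along(energies))
  cands <- cands[ord]
  energies <- energies[ord]
  rel <- energies - energies[1]
  keep_idx <- which(rel <= energy_window)
  kept <- list()
  kept_e <- numeric(0)
  for (i in keep_idx) {
    dup <- FALSE
    for (k in kept) {
      if (heavy_rmsd(cands[[i]], k) < dedup_rmsd) { dup <- TRUE; break }
    }
    if (!dup) {
      kept[[length(kept) + 1L]] <- cands[[i]]
      kept_e <- c(kept_e, rel[i])
      if (length(kept) >= max_conformers) break
    }
  }
  structure(list(molecule_id = mol$id, mol = mol, conformers = kept,
                 rel_energies = kept_e, seed = seed,
                 settings = list(max_conformers = max_conformers,
                                 energy_window = energy_window,
                                 dedup_rmsd = dedup_rmsd)),
            class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("Conformer ensemble for %s: %d conformer(s), energies 0-%.2f kcal/mol\n",
              x$molecule_id, length(x$conformers),
              max(c(0, x$rel_energies))))
  invisible(x)
}
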