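#' Perceive pharmacophore feature points on a 3D conformer
#'
#' Applies a fixed, documented rule dictionary to the heavy-atom graph and
#' one conformer's coordinates:
#'
#' * **HBD** - an O or N bearing at least one hydrogen (explicit or implied
#'   by standard valence). Placed on the heavy atom; direction points away
#'   from the centroid of its bonded neighbours.
#' * **HBA** - an O, or an N with an available lone pair (aromatic N with
#'   three ring/substituent connections, e.g. pyrrole-type, is excluded).
#'   Placed on the heavy atom.
#' * **RingArom** - each aromatic ring, placed at the ring centroid with the
#'   ring normal as direction.
#' * **HBic** - each maximal connected group of apolar atoms (non-aromatic
#'   carbon with no N/O neighbour; sulfur bonded only to carbon; halogens),
#'   placed at the group centroid.
#'
#' The rules are deterministic and every feature cites its contributing
#' atoms. Equivalent SMARTS for the atom-level rules: HBD `[#7,#8;!H0]`,
#' HBA `[#8]`/`[#7;!$([nX3])]`, apolar `[#6;!a;!$([#6]~[#7,#8])],[F,Cl,Br,I]`.
#'
#' @param x A `conformer_set` from [generate_conformers()], or a `phmol`
#'   (with `coords` supplied).
#' @param conformer Conformer index when `x` is a `conformer_set`.
#' @param coords Optional heavy-atom coordinate matrix when `x` is a `phmol`.
#' @return A data.frame with columns `kind`, `x`, `y`, `z`, `atoms` (list of
#'   contributing atom indices) and `dx`, `dy`, `dz` (unit direction, or NA).
#' @export
perceive_features <- function(x, conformer = 1, coords = NULL) {
  if (inherits(x, "conformer_set")) {
    mol <- x$mol
    if (conformer < 1 || conformer > length(x$conformers))
      stop("conformer index out of range")
    coords <- x$conformers[[conformer]]
  } else if (inherits(x, "phmol")) {
    mol <- x
    if (is.null(coords)) stop("no 3D coordinates supplied")
  } else {
    stop("x must be a conformer_set or phmol")
  }
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("no valid 3D coordinates")
  n <- length(mol$elem)
  feats <- list()
  add <- function(kind, pos, atoms, dir = c(NA, NA, NA)) {
    feats[[length(feats) + 1L]] <<- data.frame(
      kind = kind, x = pos[1], y = pos[2], z = pos[3],
      atoms = I(list(atoms)), dx = dir[1], dy = dir[2], dz = dir[3],
      stringsAsFactors = FALSE)
  }
  away_dir <- function(i) {
    nb <- mol$adjacency[[i]]
    if (length(nb) == 0L) return(c(NA, NA, NA))
    normalize(coords[i, ] - colMeans(coords[nb, , drop = FALSE]))
  }
  is_n_or_o <- mol$elem %in% c("N", "O")
  has_h <- mol$nH > 0
  # HBD
  for (i in which(is_n_or_o & has_h)) add("HBD", coords[i, ], i, away_dir(i))
  # HBA
  for (i in seq_len(n)) {
    if (mol$elem[i] == "O") add("HBA", coords[i, ], i)
    else if (mol$elem[i] == "N") {
      pyrrole_type <- mol$atom_aromatic[i] &&
        (mol$degree[i] + mol$nH[i]) >= 3
      if (!pyrrole_type) add("HBA", coords[i, ], i)
    }
  }
  # RingArom
  for (k in seq_along(mol$rings)) {
    if (!isTRUE(mol$ring_aromatic[k])) next
    ring <- mol$rings[[k]]
    ctr <- colMeans(coords[ring, , drop = FALSE])
    v1 <- coords[ring[2], ] - coords[ring[1], ]
    v2 <- coords[ring[3], ] - coords[ring[1], ]
    add("RingArom", ctr, ring, normalize(pracma_cross(v1, v2)))
  }
  # HBic: maximal connected apolar groups
  apolar <- vapply(seq_len(n), function(i) {
    e <- mol$elem[i]
    if (e %in% c("F", "Cl", "Br", "I")) return(TRUE)
    if (e == "S") return(all(mol$elem[mol$adjacency[[i]]] == "C"))
    if (e != "C") return(FALSE)
    if (mol$atom_aromatic[i]) return(FALSE)
    !any(mol$elem[mol$adjacency[[i]]] %in% c("N", "O"))
  }, logical(1))
  seen <- rep(FALSE, n)
  for (s in which(apolar)) {
    if (seen[s]) next
    comp <- s
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (a in mol$adjacency[[cur]]) {
        if (apolar[a] && !seen[a]) {
          seen[a] <- TRUE
          comp <- c(comp, a)
          queue <- c(queue, a)
        }
      }
    }
    add("HBic", colMeans(coords[comp, , drop = FALSE]), sort(comp))
  }
  out <- if (length(feats)) do.call(rbind, feats) else
    data.frame(kind = character(0), x = numeric(0), y = numeric(0),
               z = numeric(0), atoms = I(list()), dx = numeric(0),
               dy = numeric(0), dz = numeric(0))
  attr(out, "molecule_id") <- mol$id
  out
}
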