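#' Convert between IC50 (micromolar) and pIC50
#'
#' pIC50 is the negative base-10 logarithm of the IC50 expressed in molar
#' units, so for an IC50 stored in micromolar,
#' `pIC50 = -log10(ic50_um * 1e-6) = 6 - log10(ic50_um)`.
#'
#' @param ic50_um IC50 in micromolar, strictly positive.
#' @param pic50 Unitless pIC50 on the molar scale.
#' @return The converted value(s).
#' @export
to_pic50 <- function(ic50_um) {
  if (any(!is.na(ic50_um) & ic50_um <= 0))
    stop("IC50 must be strictly positive")
  6 - log10(ic50_um)
}

#' @rdname to_pic50
#' @export
to_ic50 <- function(pic50) 10^(6 - pic50)

MOLECULE_ROLES <- c("train", "test", "active", "decoy", "library")

#' Load an activity-annotated molecule table
#'
#' Reads a CSV with columns `id`, `smiles` and (optionally) `ic50_um` and
#' `role`, populating `pic50` for every record that carries an IC50. Row
#' order is preserved. Duplicate ids reject the whole file; a non-positive
#' IC50 rejects the offending record by name.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `id`, `smiles`, `ic50_um`, `pic50`,
#'   `role`.
#' @export
load_activity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "smiles")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tab$id <- as.character(tab$id)
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup)) stop("duplicate molecule id(s): ",
                        paste(unique(dup), collapse = ", "))
  if (is.null(tab$ic50_um)) tab$ic50_um <- NA_real_
  tab$ic50_um <- as.numeric(tab$ic50_um)
  bad <- !is.na(tab$ic50_um) & tab$ic50_um <= 0
  if (any(bad)) stop("non-positive IC50 for id(s): ",
                     paste(tab$id[bad], collapse = ", "))
  tab$pic50 <- ifelse(is.na(tab$ic50_um), NA_real_, to_pic50(tab$ic50_um))
  if (is.null(tab$role)) tab$role <- "train"
  bad_role <- !tab$role %in% MOLECULE_ROLES
  if (any(bad_role)) stop("unknown role(s): ",
                          paste(unique(tab$role[bad_role]), collapse = ", "))
  tab[, c("id", "smiles", "ic50_um", "pic50", "role")]
}

#' Write an activity table
#'
#' @param tab A data.frame as returned by [load_activity_table()].
#' @param path Output CSV path.
#' @export
write_activity_table <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

sdf_from_smiles <- function(smiles, id = "mol") {
  smi <- stats::setNames(as.character(smiles), as.character(id))
  sdf <- tryCatch(
    ChemmineR::smiles2sdf(methods::as(smi, "SMIset")),
    error = function(e) stop("cannot parse structure for id '", id[1], "': ",
                             conditionMessage(e), call. = FALSE))
  sdf
}

STANDARD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3, Se = 2,
                      F = 1, Cl = 1, Br = 1, I = 1, Si = 4)

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                 P = 30.974, F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904,
                 B = 10.81, Se = 78.971, Si = 28.085)

# Molecular connectivity graph for one molecule (heavy atoms only, implicit
# hydrogens counted from standard valences).
as_phmol <- function(sdf1, id = "mol", smiles = NULL) {
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  elem <- sub("_.*$", "", rownames(ab))
  n <- length(elem)
  bonds <- if (is.null(dim(bb)) || nrow(as.matrix(bb)) == 0) {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  } else {
    bbm <- as.matrix(bb)
    data.frame(a1 = as.integer(bbm[, 1]), a2 = as.integer(bbm[, 2]),
               order = as.integer(bbm[, 3]))
  }
  valsum <- rep(0L, n)
  deg <- rep(0L, n)
  for (k in seq_len(nrow(bonds))) {
    o <- bonds$order[k]
    valsum[bonds$a1[k]] <- valsum[bonds$a1[k]] + o
    valsum[bonds$a2[k]] <- valsum[bonds$a2[k]] + o
    deg[bonds$a1[k]] <- deg[bonds$a1[k]] + 1L
    deg[bonds$a2[k]] <- deg[bonds$a2[k]] + 1L
  }
  val <- STANDARD_VALENCE[elem]
  val[is.na(val)] <- 0
  nH <- pmax(0L, as.integer(val) - valsum)
  # ring perception + aromaticity
  ring_atoms <- list()
  ring_arom <- logical(0)
  atom_arom <- rep(FALSE, n)
  if (nrow(bonds) >= 3 && n >= 3) {
    rr <- tryCatch(ChemmineR::rings(sdf1, type = "all", arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(rr) && length(rr$RINGS)) {
      ring_atoms <- lapply(rr$RINGS, function(v)
        as.integer(sub("^.*_", "", v)))
      ring_arom <- as.logical(rr$AROMATIC)
      for (i in seq_along(ring_atoms)) {
        if (isTRUE(ring_arom[i])) atom_arom[ring_atoms[[i]]] <- TRUE
      }
    }
  }
  adj <- lapply(seq_len(n), function(i)
    sort(c(bonds$a2[bonds$a1 == i], bonds$a1[bonds$a2 == i])))
  structure(list(id = id, elem = elem, bonds = bonds, nH = nH, degree = deg,
                 adjacency = adj, rings = ring_atoms,
                 ring_aromatic = ring_arom, atom_aromatic = atom_arom,
                 coords2d = ab[, 1:3, drop = FALSE], sdf = sdf1,
                 smiles = smiles),
            class = "phmol")
}

#' Parse a molecular structure
#'
#' Accepts a SMILES string or an SDF (V2000) file and returns the internal
#' heavy-atom connectivity graph used by the conformer generator and feature
#' perception. Implicit hydrogen counts come from standard valences;
#' aromaticity from ring perception.
#'
#' @param structure A SMILES string, or a path to an SDF file when
#'   `format = "sdf"`.
#' @param id Molecule identifier.
#' @param format `"smiles"` (default) or `"sdf"`.
#' @return An object of class `phmol`.
#' @export
parse_structure <- function(structure, id = "mol",
                            format = c("smiles", "sdf")) {
  format <- match.arg(format)
  sdf <- if (format == "smiles") sdf_from_smiles(structure, id)
         else ChemmineR::read.SDFset(structure)
  as_phmol(sdf[[1]], id = id,
           smiles = if (format == "smiles") as.character(structure))
}

#' Read a SMILES file (one molecule per line: SMILES followed by id)
#'
#' @param path Path to the `.smi` file.
#' @return A data.frame with columns `id` and `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  smiles <- vapply(parts, `[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("mol", i)
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate molecule ids in ", path)
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Physicochemical descriptors for the rule-of-five filter
#'
#' Computes molecular weight (Da), an octanol/water partition estimate
#' (Open Babel's atom-contribution logP) and hydrogen-bond donor/acceptor
#' counts under Open Babel's default perception. Deterministic for a given
#' structure.
#'
#' @param m A SMILES string, a `phmol`, or a character vector of SMILES.
#' @param id Identifier(s) used in error messages.
#' @return A data.frame with columns `id`, `mw`, `logp`, `hbd_count`,
#'   `hba_count` (one row per molecule).
#' @export
compute_descriptors <- function(m, id = NULL) {
  if (inherits(m, "phmol")) {
    if (is.null(m$smiles)) stop("no source SMILES stored for '", m$id, "'")
    id <- m$id
    m <- m$smiles
  }
  if (is.null(id)) id <- if (!is.null(names(m))) names(m)
                         else paste0("mol", seq_along(m))
  rows <- lapply(seq_along(m), function(i) {
    pr <- tryCatch(
      ChemmineOB::forEachMol("SMILES", as.character(m[i]),
                             function(mol) ChemmineOB::prop_OB(mol))[[1]],
      error = function(e) stop("cannot compute descriptors for id '",
                               id[i], "': ", conditionMessage(e),
                               call. = FALSE))
    data.frame(id = as.character(id[i]), mw = pr$MW, logp = pr$logP,
               hbd_count = as.integer(pr$HBD),
               hba_count = as.integer(pr$HBA1), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

LIPINSKI_RULES <- c(mw = 500, logp = 5, hbd_count = 5, hba_count = 10)

#' Lipinski rule-of-five filter
#'
#' Flags poor-absorption risks using the four classical criteria: molecular
#' weight > 500 Da, logP > 5, more than 5 hydrogen-bond donors, or more than
#' 10 acceptors. All inequalities are strict, and a single violation fails
#' the molecule (the filter's rejection policy; a multi-violation policy is
#' available via `max_violations`).
#'
#' @param d Descriptors: a list or one-row data.frame with fields `mw`,
#'   `logp`, `hbd_count`, `hba_count` (see [compute_descriptors()]).
#' @param max_violations Number of violations tolerated before failing
#'   (default 0: reject on any violation).
#' @return A list with `pass` (logical) and `violations` (character vector
#'   of violated rule names among `"mw"`, `"logp"`, `"hbd_count"`,
#'   `"hba_count"`).
#' @export
lipinski_filter <- function(d, max_violations = 0) {
  vals <- vapply(names(LIPINSKI_RULES), function(f) {
    v <- d[[f]]
    if (is.null(v) || length(v) != 1L || is.na(v))
      stop("missing descriptor: ", f, call. = FALSE)
    as.numeric(v)
  }, numeric(1))
  violated <- names(LIPINSKI_RULES)[vals > LIPINSKI_RULES]
  list(pass = length(violated) <= max_violations, violations = violated)
}
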