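#' Water configuration objects
#'
#' A configuration is the single source of geometric truth: element labels,
#' Cartesian coordinates (Angstrom), optional velocities (Angstrom/fs), an
#' optional orthorhombic cell, and the molecule topology (each molecule is one
#' O followed by its two H).  Topology is supplied explicitly or inferred from
#' O-H distances below 1.3 Angstrom.
#'
#' @param species character vector of element labels ("O"/"H").
#' @param positions numeric N x 3 matrix of coordinates, Angstrom.
#' @param velocities optional N x 3 matrix, Angstrom/fs.
#' @param cell optional length-3 numeric vector of orthorhombic box lengths,
#'   Angstrom; `NULL` for clusters.
#' @param mol optional integer vector of 1-based molecule indices per atom; if
#'   missing, inferred from O-H connectivity.
#' @param check validate invariants (one O + two H per molecule, atom count a
#'   multiple of 3).
#' @return an object of class `aq_config`.
#' @export
configuration <- function(species, positions, velocities = NULL, cell = NULL,
                          mol = NULL, check = TRUE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  stopifnot(length(species) == n, ncol(positions) == 3)
  bad <- setdiff(unique(species), c("O", "H"))
  if (length(bad))
    stop("unsupported element label(s): ", paste(bad, collapse = ", "))
  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    stopifnot(length(cell) == 3, all(cell > 0))
  }
  if (is.null(mol)) mol <- infer_topology(species, positions, cell)
  mol <- as.integer(mol)
  cfg <- structure(list(species = species, positions = positions,
                        velocities = velocities, cell = cell, mol = mol),
                   class = "aq_config")
  cfg$molatoms <- if (check) molecule_table(cfg) else
    tryCatch(molecule_table(cfg), error = function(e) {
      # degenerate table for non-water systems (ion lattices, test rigs):
      # each molecule represented by its first atom
      idx <- match(unique(mol), mol)
      matrix(rep(idx, 3), ncol = 3)
    })
  if (check) validate_config(cfg)
  cfg
}

# per-molecule atom index table, columns (O, H1, H2), 1-based
molecule_table <- function(cfg) {
  nm <- max(cfg$mol)
  out <- matrix(NA_integer_, nm, 3)
  for (m in seq_len(nm)) {
    idx <- which(cfg$mol == m)
    o <- idx[cfg$species[idx] == "O"]
    h <- idx[cfg$species[idx] == "H"]
    if (length(o) != 1 || length(h) != 2)
      stop("molecule ", m, " does not have exactly one O and two H")
    out[m, ] <- c(o, h)
  }
  out
}

validate_config <- function(cfg) {
  if (nrow(cfg$positions) != 3L * nrow(cfg$molatoms))
    stop("atom count must be 3 x molecule count")
  invisible(cfg)
}

#' @export
print.aq_config <- function(x, ...) {
  cat("aq_config:", nrow(x$positions), "atoms,", nrow(x$molatoms),
      "molecules,", if (is.null(x$cell)) "cluster"
      else paste0("box ", paste(signif(x$cell, 6), collapse = " x "), " A"),
      "\n")
  invisible(x)
}

# infer molecule membership from O-H distance < 1.3 A
infer_topology <- function(species, positions, cell = NULL) {
  n <- length(species)
  oidx <- which(species == "O")
  hidx <- which(species == "H")
  if (length(hidx) != 2 * length(oidx))
    stop("need two H per O to infer water topology")
  mol <- integer(n)
  mol[oidx] <- seq_along(oidx)
  cellv <- if (is.null(cell)) numeric(0) else cell
  for (h in hidx) {
    d <- positions[oidx, , drop = FALSE] -
      matrix(positions[h, ], length(oidx), 3, byrow = TRUE)
    d <- cpp_min_image_vec(d, cellv)
    r <- sqrt(rowSums(d^2))
    k <- which(r < 1.3)
    if (length(k) != 1)
      stop("cannot assign H atom ", h, " to a unique O (found ", length(k),
           " O within 1.3 A)")
    mol[h] <- k
  }
  mol
}

# internal: 0-based views for the C++ kernels
cfg_c <- function(cfg) {
  list(pos = cfg$positions,
       elem = as.integer(cfg$species == "H"),   # 0 = O, 1 = H
       mol = cfg$mol - 1L,
       molatoms = cfg$molatoms - 1L,
       cell = if (is.null(cfg$cell)) numeric(0) else cfg$cell)
}

# largest interaction cutoff a configuration must accommodate
check_cell_cutoff <- function(cfg, cutoff) {
  if (!is.null(cfg$cell) && any(cfg$cell <= 2 * cutoff))
    stop("box too small for cutoff ", cutoff,
         " A: minimum-image convention requires all box lengths > 2 x cutoff")
  invisible(TRUE)
}

#' Minimum-image displacement between two atoms
#'
#' Shortest periodic image of `r_j - r_i` for orthorhombic cells; the plain
#' difference for clusters.  A displacement of exactly half a box length maps
#' deterministically to the negative-sign image.
#'
#' @param config an [configuration()] object.
#' @param i,j 1-based atom indices.
#' @param cutoff optional cutoff used to validate minimum-image applicability.
#' @return length-3 numeric displacement vector, Angstrom.
#' @export
minimum_image_displacement <- function(config, i, j, cutoff = NULL) {
  if (!is.null(cutoff)) check_cell_cutoff(config, cutoff)
  d <- matrix(config$positions[j, ] - config$positions[i, ], 1, 3)
  as.numeric(cpp_min_image_vec(d, if (is.null(config$cell)) numeric(0)
                               else config$cell))
}

#' Neighbor list within a cutoff
#'
#' Exact all-pairs minimum-image enumeration: every unordered pair with
#' distance at or below `cutoff`, stored symmetrically.
#'
#' @inheritParams minimum_image_displacement
#' @param cutoff cutoff, Angstrom (> 0).
#' @return a data.frame with columns `i`, `j` (both directions), `dx`, `dy`,
#'   `dz` (displacement from i to j) and `r`.
#' @export
build_neighbor_list <- function(config, cutoff) {
  stopifnot(cutoff > 0)
  check_cell_cutoff(config, cutoff)
  cc <- cfg_c(config)
  p <- cpp_neighbor_pairs(cc$pos, cc$cell, cutoff)
  if (nrow(p) == 0)
    return(data.frame(i = integer(0), j = integer(0), dx = numeric(0),
                      dy = numeric(0), dz = numeric(0), r = numeric(0)))
  out <- data.frame(i = c(p[, 1], p[, 2]) + 1L, j = c(p[, 2], p[, 1]) + 1L,
                    dx = c(p[, 3], -p[, 3]), dy = c(p[, 4], -p[, 4]),
                    dz = c(p[, 5], -p[, 5]), r = c(p[, 6], p[, 6]))
  out[order(out$i, out$j), , drop = FALSE]
}

#' Wrap molecules rigidly into the unit cell
#'
#' Translates each molecule as a rigid unit so its O atom lies in `[0, L)`;
#' intramolecular geometry is untouched.  For clusters this is a no-op with a
#' warning.
#'
#' @inheritParams minimum_image_displacement
#' @return the wrapped configuration.
#' @export
wrap_molecules <- function(config) {
  if (is.null(config$cell)) {
    warning("wrap_molecules: cluster input, nothing to wrap")
    return(config)
  }
  pos <- config$positions
  for (m in seq_len(nrow(config$molatoms))) {
    o <- config$molatoms[m, 1]
    shift <- -config$cell * floor(pos[o, ] / config$cell)
    idx <- config$molatoms[m, ]
    pos[idx, ] <- pos[idx, ] + matrix(shift, 3, 3, byrow = TRUE)
  }
  config$positions <- pos
  config
}
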