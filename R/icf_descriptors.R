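#' Interaction-classified descriptor specification
#'
#' The descriptors are radial, element-pair-resolved sums
#' `f = sum_j exp(-k_f r_ij) * s_c(r_ij)` over neighbors of one interaction
#' class, with the smooth cosine cutoff [cutoff_weight()].  Three decay
#' parameters per class probe short-, mid- and long-ranged structure.
#'
#' @param r_c radial cutoff for per-atom charge features, Angstrom.
#' @param k_f decay parameters, 1/Angstrom; positive, strictly increasing,
#'   length 3.
#' @param ct_cutoff cutoff for pairwise charge-transfer features, Angstrom.
#' @return an object of class `aq_icf_spec`.
#' @export
icf_spec <- function(r_c = 4.4, k_f = c(0.5, 1.0, 2.0), ct_cutoff = 5.5) {
  stopifnot(r_c > 0, length(k_f) == 3, all(k_f > 0), !is.unsorted(k_f,
            strictly = TRUE), ct_cutoff > 0)
  structure(list(r_c = r_c, k_f = as.numeric(k_f), ct_cutoff = ct_cutoff),
            class = "aq_icf_spec")
}

#' Smooth cosine cutoff weight
#'
#' `s_c(r) = (cos(pi r / r_c) + 1)/2` for `r <= r_c`, 0 beyond; continuously
#' differentiable at the cutoff with vanishing slope.
#'
#' @param r distances, Angstrom (>= 0).
#' @param r_c cutoff, Angstrom (> 0).
#' @return weights in `[0, 1]`.
#' @export
cutoff_weight <- function(r, r_c) {
  if (r_c <= 0) stop("r_c must be positive")
  stopifnot(all(r >= 0))
  as.numeric(cpp_cutoff_weight(as.numeric(r), r_c))
}

#' Single interaction-classified function value
#'
#' Sum of `exp(-k_f r) * s_c(r)` over the atoms of one element class in one
#' intra/intermolecular relation to the center, excluding the center itself;
#' neighbors are drawn by minimum image.
#'
#' @param config a [configuration()].
#' @param center 1-based atom index.
#' @param class element of the neighbors, "O" or "H".
#' @param scope "intra" or "inter".
#' @param k_f decay parameter, 1/Angstrom.
#' @param r_c cutoff, Angstrom.
#' @return dimensionless scalar.
#' @export
icf_value <- function(config, center, class = c("O", "H"),
                      scope = c("intra", "inter"), k_f, r_c) {
  class <- match.arg(class)
  scope <- match.arg(scope)
  n <- nrow(config$positions)
  js <- setdiff(seq_len(n), center)
  js <- js[config$species[js] == class]
  same <- config$mol[js] == config$mol[center]
  js <- js[if (scope == "intra") same else !same]
  if (!length(js)) return(0)
  d <- config$positions[js, , drop = FALSE] -
    matrix(config$positions[center, ], length(js), 3, byrow = TRUE)
  d <- cpp_min_image_vec(d, if (is.null(config$cell)) numeric(0)
                         else config$cell)
  r <- sqrt(rowSums(d^2))
  sum(exp(-k_f * r) * cutoff_weight(r, r_c))
}

#' Per-atom charge feature vectors
#'
#' 24 slots per atom: for each of the three decay parameters, the center's
#' intramolecular ICFs (classes O, H), its intermolecular ICFs (O, H), and the
#' intermolecular ICFs of the two other atoms of the same molecule (classes O,
#' H).  For an H center the sibling blocks are the O sibling then the other H;
#' for an O center the two H siblings enter as smooth symmetric power sums
#' (sum and sum of squares) so the features are invariant under H relabeling.
#'
#' @param config a [configuration()].
#' @param spec an [icf_spec()].
#' @param atoms optional subset of 1-based atom indices (default all).
#' @return numeric matrix, one row per atom, 24 columns.
#' @export
charge_feature_vector <- function(config, spec = icf_spec(), atoms = NULL) {
  cc <- cfg_c(config)
  F <- cpp_charge_features(cc$pos, cc$elem, cc$mol, cc$molatoms, cc$cell,
                           spec$k_f, spec$r_c)
  colnames(F) <- charge_feature_names(spec)
  if (!is.null(atoms)) F <- F[atoms, , drop = FALSE]
  F
}

charge_feature_names <- function(spec) {
  slots <- c("intra.O", "intra.H", "inter.O", "inter.H",
             "sib1.O", "sib1.H", "sib2.O", "sib2.H")
  as.vector(vapply(seq_along(spec$k_f), function(t)
    paste0("kf", t, ".", slots), character(8)))
}

#' Pairwise charge-transfer feature vector
#'
#' 36 slots for an ordered molecule pair (I, J): for each decay parameter, the
#' ICFs of each atom of I restricted to neighbors in J (classes O, H; the two
#' H atoms as power sums) followed by the same for J restricted to I.  All
#' kernels use `r_c = ct_cutoff`.  Swapping I and J swaps the two 18-slot
#' halves blockwise.  Returns `NULL` ("no CT pair") when the minimum-image
#' O-O distance exceeds the CT cutoff.
#'
#' @param config a [configuration()].
#' @param mol_I,mol_J 1-based molecule indices.
#' @param spec an [icf_spec()].
#' @return numeric length-36 vector, or `NULL` beyond the cutoff.
#' @export
ct_feature_vector <- function(config, mol_I, mol_J, spec = icf_spec()) {
  cc <- cfg_c(config)
  oI <- cc$molatoms[mol_I, 1] + 1L
  oJ <- cc$molatoms[mol_J, 1] + 1L
  d <- minimum_image_displacement(config, oI, oJ)
  if (sqrt(sum(d^2)) > spec$ct_cutoff) return(NULL)
  as.numeric(cpp_ct_features(cc$pos, cc$elem, cc$molatoms, cc$cell,
                             mol_I - 1L, mol_J - 1L, spec$k_f, spec$ct_cutoff))
}

#' Analytic descriptor Jacobian
#'
#' Exact derivative of every feature slot with respect to every Cartesian
#' coordinate, chained through the exponential, the cosine cutoff and the
#' interatomic distances.  `target = atom index` gives the 24 x 3N Jacobian of
#' that atom's charge features; `target = c(I, J)` the 36 x 3N Jacobian of the
#' pair CT features.
#'
#' @param config a [configuration()].
#' @param target a single atom index or a molecule pair `c(I, J)`.
#' @param spec an [icf_spec()].
#' @return numeric matrix (rows = feature slots, columns = x1 y1 z1 x2 ...).
#' @export
feature_jacobian <- function(config, target, spec = icf_spec()) {
  cc <- cfg_c(config)
  if (length(target) == 1) {
    cpp_charge_feature_jacobian(cc$pos, cc$elem, cc$mol, cc$molatoms, cc$cell,
                                spec$k_f, spec$r_c, target - 1L)
  } else {
    cpp_ct_feature_jacobian(cc$pos, cc$elem, cc$molatoms, cc$cell,
                            target[1] - 1L, target[2] - 1L, spec$k_f,
                            spec$ct_cutoff)
  }
}
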