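#' Charge sets and neutralization
#'
#' The networks predict each atom's charge independently, so the total charge
#' of a cluster or unit cell carries a small accumulative error.  Before any
#' electrostatics the charges are shifted by their mean,
#' `Delta q = sum(q_i)/N`, which restores exact neutrality.
#'
#' @param charges numeric vector of per-atom charges, e.
#' @return a list of class `aq_charge_set` with elements `q` (shifted
#'   charges), `dq_shift` (the recorded shift, e) and `neutralized`.
#' @export
neutralize <- function(charges) {
  q <- as.numeric(charges)
  stopifnot(length(q) >= 1)
  dq <- mean(q)
  structure(list(q = q - dq, dq_shift = dq, neutralized = TRUE),
            class = "aq_charge_set")
}

#' Predict per-atom charges with the element-specific networks
#'
#' Builds the 24-slot descriptor of every atom, evaluates the O network on O
#' atoms and the H network on H atoms, and (by default) applies the
#' neutralization shift.
#'
#' @param config a [configuration()].
#' @param nets list with elements `O` and `H`, each an [dense_network()].
#' @param spec an [icf_spec()].
#' @param neutralize_total apply the mean shift (default TRUE).
#' @return an `aq_charge_set` (see [neutralize()]); the raw unshifted charges
#'   are kept in element `q_raw`.
#' @export
predict_charges <- function(config, nets, spec = icf_spec(),
                            neutralize_total = TRUE) {
  F <- charge_feature_vector(config, spec)
  q <- numeric(nrow(F))
  isO <- config$species == "O"
  if (any(isO)) q[isO] <- forward_charge(nets$O, F[isO, , drop = FALSE])
  if (any(!isO)) q[!isO] <- forward_charge(nets$H, F[!isO, , drop = FALSE])
  out <- if (neutralize_total) neutralize(q) else
    structure(list(q = q, dq_shift = 0, neutralized = FALSE),
              class = "aq_charge_set")
  out$q_raw <- q
  out
}

#' Predict intermolecular charge transfer for one molecule pair
#'
#' Antisymmetrized network prediction
#' `delta_q_IJ = s_c(r_OO; ct_cutoff) * (g(F_IJ) - g(F_JI)) / 2`, so
#' `delta_q_IJ = -delta_q_JI` holds by construction and the value vanishes
#' smoothly at the CT cutoff.  Positive values denote electron flow from I to
#' J.  Pairs whose minimum-image O-O distance exceeds the cutoff have no CT.
#'
#' @param net the pair CT network (36 inputs).
#' @param config a [configuration()].
#' @param mol_I,mol_J 1-based molecule indices.
#' @param spec an [icf_spec()].
#' @return transferred charge, e (0 beyond the cutoff).
#' @export
predict_pair_ct <- function(net, config, mol_I, mol_J, spec = icf_spec()) {
  F <- ct_feature_vector(config, mol_I, mol_J, spec)
  if (is.null(F)) return(0)
  Fswap <- c(F[19:36], F[1:18])
  oI <- config$molatoms[mol_I, 1]; oJ <- config$molatoms[mol_J, 1]
  rOO <- sqrt(sum(minimum_image_displacement(config, oI, oJ)^2))
  gate <- cutoff_weight(rOO, spec$ct_cutoff)
  gate * 0.5 * (forward_charge(net, F) - forward_charge(net, Fswap))
}

#' All charge-transfer pairs of a configuration
#'
#' @inheritParams predict_pair_ct
#' @return data.frame with columns `I`, `J`, `dq` (e); `dq > 0` means
#'   electron flow I to J.
#' @export
predict_ct_set <- function(net, config, spec = icf_spec()) {
  cc <- cfg_c(config)
  p <- cpp_ct_pair_list(cc$pos, cc$molatoms, cc$cell, spec$ct_cutoff)
  if (nrow(p) == 0)
    return(data.frame(I = integer(0), J = integer(0), dq = numeric(0)))
  dq <- vapply(seq_len(nrow(p)), function(k)
    predict_pair_ct(net, config, p[k, 1] + 1L, p[k, 2] + 1L, spec), 0)
  data.frame(I = p[, 1] + 1L, J = p[, 2] + 1L, dq = dq)
}

#' CM5 model parameters
#'
#' Pairwise correction coefficients `T(Z, Z')` (antisymmetric), the global
#' exponential decay `alpha`, and covalent radii, as published for the CM5
#' model.  Only H and O are parameterized here; the H-O pair coefficient is
#' the published special value 0.1671 e, same-element pairs are zero.
#'
#' @param alpha decay, 1/Angstrom.
#' @param T_HO H-O pair coefficient, e (sign: added to the H atom).
#' @param radii named covalent radii, Angstrom.
#' @return an object of class `aq_cm5_params`.
#' @export
cm5_params <- function(alpha = 2.474, T_HO = 0.1671,
                       radii = c(H = 0.32, O = 0.63)) {
  stopifnot(alpha > 0)
  structure(list(alpha = alpha, T_HO = T_HO, radii = radii),
            class = "aq_cm5_params")
}

#' Map Hirshfeld charges to CM5 charges
#'
#' `q_i^CM5 = q_i^HPA + sum_{j != i} T(Z_i, Z_j) exp(-alpha (r_ij - R_i -
#' R_j))`.  The pairwise coefficients are antisymmetric, so the molecular
#' total charge is preserved exactly.
#'
#' @param hpa numeric vector of Hirshfeld charges, one per atom, e.
#' @param config a [configuration()].
#' @param params a [cm5_params()].
#' @return numeric vector of CM5 charges, e.
#' @export
cm5_from_hirshfeld <- function(hpa, config, params = cm5_params()) {
  n <- nrow(config$positions)
  stopifnot(length(hpa) == n)
  missing_el <- setdiff(unique(config$species), names(params$radii))
  if (length(missing_el))
    stop("no CM5 parameters for element(s): ",
         paste(missing_el, collapse = ", "))
  q <- as.numeric(hpa)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    Ti <- 0
    if (config$species[i] == "H" && config$species[j] == "O") Ti <- params$T_HO
    if (config$species[i] == "O" && config$species[j] == "H") Ti <- -params$T_HO
    if (Ti == 0) next
    d <- minimum_image_displacement(config, i, j)
    r <- sqrt(sum(d^2))
    Rz <- params$radii[[config$species[i]]] + params$radii[[config$species[j]]]
    q[i] <- q[i] + Ti * exp(-params$alpha * (r - Rz))
  }
  q
}
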