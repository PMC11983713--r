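#' Surrogate label generator parameters
#'
#' The surrogate emulates the statistical structure of environment-dependent
#' atomic charges and hydrogen-bond charge transfer: smooth, local,
#' rigid-motion invariant functions of interatomic distances with magnitudes
#' resembling condensed-phase water charges.  It replaces unavailable
#' quantum-chemistry labels so the train/predict/simulate loop is fully
#' exercisable.
#'
#' @param q_H_base base H charge, e (the O base is `-2 q_H_base`).
#' @param a polarization amplitude, e.
#' @param b polarization decay, 1/Angstrom.
#' @param c_ct charge-transfer amplitude, e.
#' @param lambda CT decay, 1/Angstrom (chosen so pair CT at a 5.5 A
#'   hydrogen-bond distance is around 1e-5 of the amplitude).
#' @param sigma_noise Gaussian label noise, e.
#' @param r_c polarization cutoff, A.
#' @param ct_cutoff CT cutoff, A.
#' @return an object of class `aq_surrogate_params`.
#' @export
surrogate_params <- function(q_H_base = 0.41, a = 0.05, b = 1.5,
                             c_ct = 0.02, lambda = 2.5, sigma_noise = 0.002,
                             r_c = 4.4, ct_cutoff = 5.5) {
  stopifnot(a >= 0, c_ct >= 0, sigma_noise >= 0)
  structure(list(q_H_base = q_H_base, a = a, b = b, c_ct = c_ct,
                 lambda = lambda, sigma_noise = sigma_noise, r_c = r_c,
                 ct_cutoff = ct_cutoff), class = "aq_surrogate_params")
}

#' Sample cluster configurations by gas-phase MD
#'
#' NVT cluster dynamics with the SPC/FW backend at the stated temperature;
#' frames are recorded at a fixed stride after equilibration and are
#' reproducible from the seed.  Frames with an evaporated molecule (O beyond
#' `radius_bound` from the center of mass) are discarded and counted.
#'
#' @param n_molecules molecules per cluster.
#' @param n_frames frames to return.
#' @param T_K temperature, K.
#' @param seed integer seed.
#' @param stride_fs spacing between recorded frames, fs.
#' @param equil_fs equilibration span before recording, fs.
#' @param dt time step, fs.
#' @param radius_bound evaporation radius, A; default scales with cluster
#'   size.
#' @return list of configurations; attribute `"n_discarded"` counts dropped
#'   frames.
#' @export
sample_cluster_configurations <- function(n_molecules, n_frames,
                                          T_K = 298.15, seed = 1L,
                                          stride_fs = 40, equil_fs = 2000,
                                          dt = 1, radius_bound = NULL) {
  if (n_frames == 0) return(list())
  stopifnot(n_molecules >= 1)
  if (is.null(radius_bound)) radius_bound <- 4 + 2.2 * n_molecules^(1 / 3) * 2
  cfg <- build_water_cluster(n_molecules, seed = seed)
  be <- energy_backend("spcfw")
  # short minimization to remove lattice strain, then equilibrate
  cfg <- minimize(cfg, be, tol = 1, max_rounds = 2, maxit = 200)$config
  steps <- ceiling(equil_fs / dt) + ceiling(n_frames * stride_fs / dt)
  traj <- run_md(cfg, be, ensemble = "NVT", T_K = T_K, dt = dt,
                 steps = steps, stride = round(stride_fs / dt), seed = seed)
  skip <- ceiling(equil_fs / stride_fs)
  frames <- traj$frames[(skip + 1):length(traj$frames)]
  keep <- vapply(frames, function(f) {
    m <- atom_masses(f)
    com <- colSums(f$positions * m) / sum(m)
    o <- f$positions[f$molatoms[, 1], , drop = FALSE]
    max(sqrt(rowSums(sweep(o, 2, com)^2))) <= radius_bound
  }, TRUE)
  out <- frames[keep]
  if (length(out) > n_frames) out <- out[seq_len(n_frames)]
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Rough initial water cluster on a jittered cubic grid
#'
#' @param n_molecules molecule count.
#' @param spacing grid spacing, A.
#' @param seed seed for orientations and jitter.
#' @return a cluster [configuration()].
#' @export
build_water_cluster <- function(n_molecules, spacing = 3.1, seed = 1L) {
  set.seed(seed)
  k <- ceiling(n_molecules^(1 / 3))
  grid <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))
  grid <- as.matrix(grid[seq_len(n_molecules), ]) * spacing
  grid <- sweep(grid, 2, colMeans(grid))
  pos <- NULL; species <- character(0)
  for (m in seq_len(n_molecules)) {
    mono <- water_monomer()
    R <- random_rotation()
    p <- mono$positions %*% t(R)
    p <- sweep(p, 2, grid[m, ] + runif(3, -0.3, 0.3), "+")
    pos <- rbind(pos, p)
    species <- c(species, mono$species)
  }
  configuration(species, pos)
}

random_rotation <- function() {
  # uniform random rotation from a QR decomposition
  repeat {
    M <- matrix(rnorm(9), 3)
    qr_ <- qr(M)
    R <- qr.Q(qr_)
    R <- R %*% diag(sign(diag(qr.R(qr_))))
    if (det(R) > 0) return(R)
  }
}

#' Surrogate per-atom charges
#'
#' `q_H = q_H_base + a * sum_{O' intermolecular} exp(-b r_HO') s_c(r_HO';
#' r_c)`; each molecule's O charge balances its two H charges and absorbs the
#' molecule's net surrogate charge transfer, so per-molecule charges are
#' neutral before CT and shifted by the CT sum after it.  Optional Gaussian
#' noise is drawn from the stated seed.  Labels are deterministic, local and
#' rigid-motion invariant.
#'
#' @param config a [configuration()].
#' @param params an [surrogate_params()].
#' @param seed seed for the noise draw (only used when `sigma_noise > 0`).
#' @return numeric per-atom charge vector, e.
#' @export
surrogate_charges <- function(config, params = surrogate_params(),
                              seed = NULL) {
  n <- nrow(config$positions)
  q <- numeric(n)
  ma <- config$molatoms
  cellv <- if (is.null(config$cell)) numeric(0) else config$cell
  oidx <- ma[, 1]
  for (i in which(config$species == "H")) {
    oth <- oidx[config$mol[oidx] != config$mol[i]]
    if (length(oth)) {
      d <- config$positions[oth, , drop = FALSE] -
        matrix(config$positions[i, ], length(oth), 3, byrow = TRUE)
      d <- cpp_min_image_vec(d, cellv)
      r <- sqrt(rowSums(d^2))
      q[i] <- params$a * sum(exp(-params$b * r) *
                               cutoff_weight(r, params$r_c))
    }
    q[i] <- q[i] + params$q_H_base
  }
  ct <- surrogate_ct_set(config, params)
  qmol_ct <- numeric(nrow(ma))
  if (nrow(ct) > 0) for (k in seq_len(nrow(ct))) {
    qmol_ct[ct$I[k]] <- qmol_ct[ct$I[k]] + ct$dq[k]
    qmol_ct[ct$J[k]] <- qmol_ct[ct$J[k]] - ct$dq[k]
  }
  for (m in seq_len(nrow(ma)))
    q[ma[m, 1]] <- -(q[ma[m, 2]] + q[ma[m, 3]]) + qmol_ct[m]
  if (params$sigma_noise > 0) {
    if (!is.null(seed)) set.seed(seed)
    q <- q + rnorm(n, sd = params$sigma_noise)
  }
  q
}

#' Surrogate pairwise charge transfer
#'
#' Antisymmetric by construction:
#' `dq_IJ = c_ct * [sum_{H in I, O in J} K(r) - sum_{H in J, O in I} K(r)]`
#' with `K(r) = exp(-lambda r) s_c(r; ct_cutoff)`.  For a hydrogen-bonded
#' pair the donor's short H...O contact dominates, giving a sign consistent
#' with electron flow donor to acceptor; for a symmetric side-by-side pair
#' the two roles cancel.
#'
#' @param config a [configuration()].
#' @param mol_I,mol_J 1-based molecule indices.
#' @param params an [surrogate_params()].
#' @return transferred charge, e (0 beyond the CT cutoff).
#' @export
surrogate_ct <- function(config, mol_I, mol_J, params = surrogate_params()) {
  ma <- config$molatoms
  cellv <- if (is.null(config$cell)) numeric(0) else config$cell
  oo <- minimum_image_displacement(config, ma[mol_I, 1], ma[mol_J, 1])
  if (sqrt(sum(oo^2)) > params$ct_cutoff) return(0)
  K <- function(h_atoms, o_atom) {
    d <- config$positions[h_atoms, , drop = FALSE] -
      matrix(config$positions[o_atom, ], length(h_atoms), 3, byrow = TRUE)
    d <- cpp_min_image_vec(d, cellv)
    r <- sqrt(rowSums(d^2))
    sum(exp(-params$lambda * r) * cutoff_weight(r, params$ct_cutoff))
  }
  params$c_ct * (K(ma[mol_I, 2:3], ma[mol_J, 1]) -
                 K(ma[mol_J, 2:3], ma[mol_I, 1]))
}

# all surrogate CT pairs of a configuration
surrogate_ct_set <- function(config, params = surrogate_params()) {
  cc <- cfg_c(config)
  p <- cpp_ct_pair_list(cc$pos, cc$molatoms, cc$cell, params$ct_cutoff)
  if (nrow(p) == 0)
    return(data.frame(I = integer(0), J = integer(0), dq = numeric(0),
                      r_OO = numeric(0)))
  dq <- vapply(seq_len(nrow(p)), function(k)
    surrogate_ct(config, p[k, 1] + 1L, p[k, 2] + 1L, params), 0)
  data.frame(I = p[, 1] + 1L, J = p[, 2] + 1L, dq = dq, r_OO = p[, 3])
}

#' Build a labelled training set from sampled clusters
#'
#' Generates cluster configurations, computes descriptor features and
#' surrogate labels for every atom (and CT labels for every molecule pair
#' within the CT cutoff), and splits cluster-wise into train / validation /
#' test with the 8000/50/remainder proportions scaled to the requested pool.
#'
#' @param n_clusters configurations to generate.
#' @param cluster_size molecules per cluster.
#' @param params an [surrogate_params()].
#' @param spec an [icf_spec()].
#' @param seed integer seed (sampling, noise, split).
#' @param T_K sampling temperature, K.
#' @return list of class `aq_dataset`: per-element feature matrices and
#'   labels (`O`, `H` with `X`, `y`, `split`), CT table (`CT` with `X`
#'   36-col, `y`, `split`), the generator settings, and the cluster split
#'   assignment.
#' @export
make_training_set <- function(n_clusters, cluster_size = 25,
                              params = surrogate_params(),
                              spec = icf_spec(), seed = 1L, T_K = 298.15) {
  if (n_clusters == 0)
    return(structure(list(O = NULL, H = NULL, CT = NULL, params = params,
                          spec = spec, seed = seed), class = "aq_dataset"))
  frames <- sample_cluster_configurations(cluster_size, n_clusters,
                                          T_K = T_K, seed = seed)
  n_clusters <- length(frames)
  # cluster-wise split in the training/validation proportions of an
  # 8000/50/remainder protocol on a 20000 pool, scaled to this pool
  set.seed(seed + 7L)
  ord <- sample.int(n_clusters)
  n_tr <- max(1, round(0.4 * n_clusters))
  n_va <- max(1, min(50, round(0.0025 * n_clusters * 20)))
  if (n_tr + n_va >= n_clusters) n_va <- max(1, n_clusters - n_tr)
  split <- rep("test", n_clusters)
  split[ord[seq_len(n_tr)]] <- "train"
  split[ord[n_tr + seq_len(n_va)]] <- "val"
  lXO <- lXH <- lXCT <- vector("list", n_clusters)
  lyO <- lyH <- lyCT <- lrCT <- vector("list", n_clusters)
  lsO <- lsH <- lsCT <- vector("list", n_clusters)
  for (k in seq_len(n_clusters)) {
    f <- frames[[k]]
    Fk <- charge_feature_vector(f, spec)
    qk <- surrogate_charges(f, params, seed = seed + 1000L + k)
    isO <- f$species == "O"
    lXO[[k]] <- Fk[isO, , drop = FALSE]
    lXH[[k]] <- Fk[!isO, , drop = FALSE]
    lyO[[k]] <- qk[isO]; lyH[[k]] <- qk[!isO]
    lsO[[k]] <- rep(split[k], sum(isO))
    lsH[[k]] <- rep(split[k], sum(!isO))
    ct <- surrogate_ct_set(f, params)
    if (nrow(ct) > 0) {
      Fct <- matrix(0, 2 * nrow(ct), 36)
      for (p in seq_len(nrow(ct))) {
        Fp <- ct_feature_vector(f, ct$I[p], ct$J[p], spec)
        Fct[2 * p - 1, ] <- Fp
        Fct[2 * p, ] <- c(Fp[19:36], Fp[1:18])
      }
      lXCT[[k]] <- Fct
      lyCT[[k]] <- as.vector(rbind(ct$dq, -ct$dq))
      lrCT[[k]] <- rep(ct$r_OO, each = 2)
      lsCT[[k]] <- rep(split[k], 2 * nrow(ct))
    }
  }
  structure(list(
    O = list(X = do.call(rbind, lXO), y = unlist(lyO), split = unlist(lsO)),
    H = list(X = do.call(rbind, lXH), y = unlist(lyH), split = unlist(lsH)),
    CT = list(X = do.call(rbind, lXCT), y = unlist(lyCT),
              split = unlist(lsCT), r_OO = unlist(lrCT)),
    cluster_split = split, params = params, spec = spec, seed = seed),
    class = "aq_dataset")
}
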