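#' Radial distribution function
#'
#' Standard histogram estimator over periodic frames, normalized by the
#' ideal-gas shell counts `4 pi r^2 dr rho`.
#'
#' @param traj an `aq_trajectory` or list of periodic configurations.
#' @param pair length-2 character, e.g. `c("O", "O")`.
#' @param dr bin width, Angstrom.
#' @param r_max histogram range, Angstrom; must not exceed half the smallest
#'   box length.
#' @return data.frame with columns `r` (bin centers, A) and `g`.
#' @export
radial_distribution <- function(traj, pair = c("O", "O"), dr = 0.05,
                                r_max = NULL) {
  frames <- if (inherits(traj, "aq_trajectory")) traj$frames else traj
  cfg1 <- frames[[1]]
  if (is.null(cfg1$cell)) stop("radial_distribution needs periodic frames")
  L <- cfg1$cell
  if (is.null(r_max)) r_max <- min(L) / 2
  if (r_max > min(L) / 2 + 1e-9)
    stop("r_max exceeds half the smallest box length")
  edges <- seq(0, r_max, by = dr)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + dr)
  counts <- numeric(length(edges) - 1)
  same <- identical(pair[1], pair[2])
  for (cfg in frames) {
    idx <- which(cfg$species %in% pair)
    cellv <- if (is.null(cfg$cell)) numeric(0) else cfg$cell
    pp <- cpp_neighbor_pairs(cfg$positions[idx, , drop = FALSE], cellv,
                             max(edges))
    if (nrow(pp) > 0) {
      i1 <- idx[pp[, 1] + 1]; j1 <- idx[pp[, 2] + 1]
      keep <- (cfg$species[i1] == pair[1] & cfg$species[j1] == pair[2]) |
              (cfg$species[i1] == pair[2] & cfg$species[j1] == pair[1])
      h <- graphics::hist(pp[keep, 6], breaks = edges, plot = FALSE)$counts
      counts <- counts + (if (same) 2 else 1) * h  # both directions
    }
  }
  nA <- sum(frames[[1]]$species == pair[1])
  nB <- sum(frames[[1]]$species == pair[2])
  V <- prod(L)
  centers <- edges[-1] - dr / 2
  shell <- 4 * pi * centers^2 * dr
  rhoB <- if (same) (nA - 1) / V else nB / V
  g <- counts / (length(frames) * nA) / (shell * rhoB)
  data.frame(r = centers, g = g)
}

#' Per-molecule dipole moments
#'
#' `mu_I = sum_{i in I} q_i (r_i - r_origin)` with the origin at the nuclear
#' charge center `sum Z_i r_i / sum Z_i` (Z_O = 8, Z_H = 1), the convention
#' that keeps dipoles of partially charged molecules well defined.
#'
#' @param config a [configuration()].
#' @param charges per-atom charges, e (an `aq_charge_set` or numeric).
#' @return data.frame with per-molecule `mux`, `muy`, `muz`, `mu` (Debye) and
#'   the molecular net charge `q_mol` (e).
#' @export
molecular_dipole <- function(config, charges) {
  q <- if (inherits(charges, "aq_charge_set")) charges$q else
    as.numeric(charges)
  Z <- ifelse(config$species == "O", 8, 1)
  ma <- config$molatoms
  out <- data.frame(mux = numeric(nrow(ma)), muy = 0, muz = 0, mu = 0,
                    q_mol = 0)
  for (m in seq_len(nrow(ma))) {
    idx <- ma[m, ]
    pos <- config$positions[idx, , drop = FALSE]
    org <- colSums(pos * Z[idx]) / sum(Z[idx])
    mu <- colSums((pos - matrix(org, 3, 3, byrow = TRUE)) * q[idx]) *
      .const$debye
    out[m, c("mux", "muy", "muz")] <- mu
    out$mu[m] <- sqrt(sum(mu^2))
    out$q_mol[m] <- sum(q[idx])
  }
  out
}

#' Infrared spectrum from the dipole autocorrelation
#'
#' Fourier transform of the total-dipole autocorrelation function with a Hann
#' window and (optionally) the harmonic quantum correction factor.  The
#' frequency axis follows from the recording stride.
#'
#' @param dipoles numeric matrix of total dipole vectors per frame (n x 3),
#'   or a vector for a scalar signal.
#' @param dt_fs time between frames, fs.
#' @param T_K temperature for the quantum correction, K.
#' @param correction `"harmonic"` or `"none"`.
#' @param nu_max maximum wavenumber retained, 1/cm.
#' @return data.frame with `nu` (1/cm) and `intensity` (arbitrary units).
#' @export
ir_spectrum <- function(dipoles, dt_fs, T_K = 298.15,
                        correction = c("harmonic", "none"), nu_max = 4500) {
  correction <- match.arg(correction)
  M <- if (is.null(dim(dipoles))) matrix(dipoles, ncol = 1) else
    as.matrix(dipoles)
  n <- nrow(M)
  if (n < 16) warning("trajectory too short for a resolved spectrum")
  M <- sweep(M, 2, colMeans(M))
  nlag <- floor(n / 2)
  acfsum <- numeric(nlag + 1)
  for (c_ in seq_len(ncol(M))) {
    a <- acf(M[, c_], lag.max = nlag, plot = FALSE, demean = FALSE,
             type = "covariance")$acf[, 1, 1]
    acfsum <- acfsum + a
  }
  w <- 0.5 * (1 + cos(pi * (0:nlag) / nlag))  # Hann
  padded <- c(acfsum * w, rep(0, nlag + 1))
  sp <- Re(fft(padded))[seq_len(nlag + 1)]
  # frequency axis: cycles per fs -> 1/cm  (1 cycle/fs = 33356.41 1/cm)
  freq <- (0:nlag) / (length(padded) * dt_fs)
  nu <- freq * 33356.40952
  inten <- sp
  if (correction == "harmonic") {
    # beta h nu / (1 - exp(-beta h nu)), h nu in kcal/mol: nu_cm * 2.8591e-3
    bh <- (nu * 2.8591e-3) / (.const$kB * T_K)
    qc <- ifelse(bh > 1e-12, bh / (1 - exp(-bh)), 1)
    inten <- inten * qc
  }
  keep <- nu <= nu_max
  data.frame(nu = nu[keep], intensity = inten[keep])
}

#' Self-diffusion coefficient from the Einstein relation
#'
#' Least-squares slope of the mean-squared displacement over a stated window;
#' `D = slope / 6` converted to `1e-5 cm^2/s`.  Coordinates must be unwrapped
#' (ballistic short-time behavior is reported for diagnostics).
#'
#' @param traj an `aq_trajectory` or list of configurations (unwrapped).
#' @param dt_fs time between frames, fs (taken from the trajectory if
#'   available).
#' @param window fraction `c(lo, hi)` of the lag range used for the fit.
#' @param species restrict to one element (default O).
#' @return list with `D` (1e-5 cm^2/s), the MSD table, and the fit window.
#' @export
self_diffusion <- function(traj, dt_fs = NULL, window = c(0.2, 0.8),
                           species = "O") {
  frames <- if (inherits(traj, "aq_trajectory")) traj$frames else traj
  if (is.null(dt_fs))
    dt_fs <- if (inherits(traj, "aq_trajectory")) traj$dt * traj$stride else
      stop("dt_fs required")
  sel <- which(frames[[1]]$species == species)
  n <- length(frames)
  X <- vapply(frames, function(f) f$positions[sel, , drop = FALSE],
              frames[[1]]$positions[sel, , drop = FALSE])
  nlag <- floor(n / 2)
  msd <- numeric(nlag)
  for (lag in seq_len(nlag)) {
    d <- X[, , (1 + lag):n, drop = FALSE] - X[, , 1:(n - lag), drop = FALSE]
    msd[lag] <- mean(apply(d, 3, function(m) mean(rowSums(m^2))))
  }
  tlag <- seq_len(nlag) * dt_fs
  lo <- max(1, floor(window[1] * nlag)); hi <- max(lo + 1,
                                                   floor(window[2] * nlag))
  fit <- lm(msd[lo:hi] ~ tlag[lo:hi])
  slope <- coef(fit)[2]              # A^2/fs
  D <- slope / 6 * 1e4               # A^2/fs = 1e4 x 1e-5 cm^2/s
  list(D = as.numeric(D), msd = data.frame(t_fs = tlag, msd = msd),
       window = c(lo, hi) * dt_fs)
}

#' Orientational tetrahedral order parameter
#'
#' Errington-Debenedetti measure over the four nearest oxygen neighbors of
#' each oxygen: `q = 1 - 3/8 sum_{j<k} (cos psi_jk + 1/3)^2`; 1 for a perfect
#' tetrahedron, 0 on average for random directions.
#'
#' @param config a [configuration()].
#' @return list with per-oxygen `q` (NA where fewer than 4 O neighbors),
#'   `mean_q`, and `n_excluded`.
#' @export
tetrahedral_order <- function(config) {
  oidx <- which(config$species == "O")
  pos <- config$positions[oidx, , drop = FALSE]
  cellv <- if (is.null(config$cell)) numeric(0) else config$cell
  nO <- length(oidx)
  q <- rep(NA_real_, nO)
  for (a in seq_len(nO)) {
    d <- sweep(pos, 2, pos[a, ])
    d <- cpp_min_image_vec(d, cellv)
    r <- sqrt(rowSums(d^2)); r[a] <- Inf
    if (sum(is.finite(r)) < 4) next
    nn <- order(r)[1:4]
    u <- d[nn, , drop = FALSE] / r[nn]
    s <- 0
    for (j in 1:3) for (k in (j + 1):4)
      s <- s + (sum(u[j, ] * u[k, ]) + 1 / 3)^2
    q[a] <- 1 - 3 / 8 * s
  }
  list(q = q, mean_q = mean(q, na.rm = TRUE), n_excluded = sum(is.na(q)))
}

#' Heat of vaporization from the mean liquid interaction energy
#'
#' `H_vap = -<E_int> + R T`, the ideal-gas relation for a per-molecule
#' interaction energy.
#'
#' @param E_int mean per-molecule interaction energy, kcal/mol.
#' @param T_K temperature, K.
#' @return kcal/mol.
#' @export
heat_of_vaporization <- function(E_int, T_K = 298.15) {
  -E_int + .const$R_gas * T_K
}

#' Droplet shell statistics: charge density and hydrogen proportion
#'
#' Atoms are binned by distance to the instantaneous center of mass of each
#' frame.  Per shell: the volume charge density VCD (net charge over the
#' exact spherical-shell volume, e/nm^3), the proportion of hydrogen atoms
#' PHA (%), a molecular-charge histogram, and the VCD computed from net
#' molecular charges of molecules whose centers of mass fall in the shell.
#'
#' @param traj an `aq_trajectory` or list of cluster configurations with
#'   charges (`traj$charges` or a `charges` list argument).
#' @param shell_width shell width, Angstrom.
#' @param charges optional list of per-frame charge vectors.
#' @param r_max outer radius; default covers all atoms.
#' @param mol_charge_breaks breaks for the molecular-charge histogram, e.
#' @return list of class `aq_layer_stats`: data.frame `shells` with columns
#'   `r_lo`, `r_hi`, `vcd` (e/nm^3), `pha` (%), `n_atoms`, `vcd_mol`
#'   (e/nm^3); `mol_charge_hist` (matrix shells x breaks); `pha_total` (%);
#'   `total_charge` (e).  Empty shells carry NA, not zero.
#' @export
layer_statistics <- function(traj, shell_width = 1, charges = NULL,
                             r_max = NULL,
                             mol_charge_breaks = seq(-0.1, 0.1, by = 0.01)) {
  frames <- if (inherits(traj, "aq_trajectory")) traj$frames else traj
  if (is.null(charges))
    charges <- if (inherits(traj, "aq_trajectory")) traj$charges else
      lapply(frames, attr, "charges")
  if (is.null(charges[[1]])) stop("layer_statistics needs per-atom charges")
  m1 <- atom_masses(frames[[1]])
  if (is.null(r_max)) {
    r_max <- 0
    for (f in frames) {
      com <- colSums(f$positions * m1) / sum(m1)
      r_max <- max(r_max, sqrt(max(rowSums(sweep(f$positions, 2, com)^2))))
    }
    r_max <- ceiling(r_max / shell_width) * shell_width
  }
  edges <- seq(0, r_max, by = shell_width)
  ns <- length(edges) - 1
  qsum <- hsum <- asum <- qmolsum <- molcnt <- numeric(ns)
  hist_mat <- matrix(0, ns, length(mol_charge_breaks) - 1)
  total_charge <- 0
  for (k in seq_along(frames)) {
    f <- frames[[k]]; q <- charges[[k]]
    com <- colSums(f$positions * m1) / sum(m1)
    r <- sqrt(rowSums(sweep(f$positions, 2, com)^2))
    bin <- pmin(ns, findInterval(r, edges, rightmost.closed = TRUE))
    for (b in unique(bin)) {
      sel <- bin == b
      qsum[b] <- qsum[b] + sum(q[sel])
      hsum[b] <- hsum[b] + sum(f$species[sel] == "H")
      asum[b] <- asum[b] + sum(sel)
    }
    total_charge <- total_charge + sum(q)
    # molecular binning by center of mass
    ma <- f$molatoms
    for (mm in seq_len(nrow(ma))) {
      idx <- ma[mm, ]
      mcom <- colSums(f$positions[idx, ] * m1[idx]) / sum(m1[idx])
      rb <- sqrt(sum((mcom - com)^2))
      b <- min(ns, findInterval(rb, edges, rightmost.closed = TRUE))
      if (b < 1) b <- 1
      qm <- sum(q[idx])
      qmolsum[b] <- qmolsum[b] + qm
      molcnt[b] <- molcnt[b] + 1
      hb <- findInterval(qm, mol_charge_breaks, rightmost.closed = TRUE)
      if (hb >= 1 && hb <= ncol(hist_mat))
        hist_mat[b, hb] <- hist_mat[b, hb] + 1
    }
  }
  nf <- length(frames)
  vol_nm3 <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3) / 1000
  shells <- data.frame(
    r_lo = edges[-length(edges)], r_hi = edges[-1],
    vcd = ifelse(asum > 0, qsum / nf / vol_nm3, NA),
    pha = ifelse(asum > 0, 100 * hsum / asum, NA),
    n_atoms = asum / nf,
    vcd_mol = ifelse(molcnt > 0, qmolsum / nf / vol_nm3, NA))
  structure(list(shells = shells, mol_charge_hist = hist_mat,
                 mol_charge_breaks = mol_charge_breaks,
                 pha_total = 100 * sum(hsum) / sum(asum),
                 total_charge = total_charge / nf),
            class = "aq_layer_stats")
}

#' Write an observable table as TSV with units in the header
#'
#' @param df a data.frame from one of the observable functions.
#' @param path output path.
#' @param units named character vector appended to column names.
#' @export
write_observable <- function(df, path, units = NULL) {
  if (!is.null(units)) {
    nm <- names(df)
    for (k in seq_along(nm))
      if (nm[k] %in% names(units))
        nm[k] <- paste0(nm[k], ".", units[[nm[k]]])
    names(df) <- nm
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
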