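#' SPC/FW parameters
#'
#' Published constants of the flexible SPC/FW 3-site water model: charges
#' `q_O = -0.82 e`, `q_H = +0.41 e`, equilibrium geometry `r0 = 1.012 A`,
#' `theta0 = 113.24 deg`, harmonic constants 1059.162 kcal/mol/A^2 and 75.90
#' kcal/mol/rad^2 (defined there with a factor 1/2, stored here in this
#' package's no-1/2 convention as 529.581 and 37.95), and 12-6 Lennard-Jones
#' `eps_OO = 0.1554253 kcal/mol`, `sigma_OO = 3.165492 A`.
#'
#' @param q_O,q_H charges, e (must sum to zero over a molecule).
#' @param r0 equilibrium bond length, Angstrom.
#' @param theta0 equilibrium angle, degrees.
#' @param k_b,k_a harmonic constants in the no-1/2 convention.
#' @param epsilon_OO,sigma_OO 12-6 Lennard-Jones parameters.
#' @param k_e Coulomb constant.
#' @param r_cut real-space cutoff used under periodic boundaries, A.
#' @param ewald_accuracy Ewald accuracy target.
#' @return an object of class `aq_spcfw_params`.
#' @export
spcfw_params <- function(q_O = -0.82, q_H = 0.41, r0 = 1.012,
                         theta0 = 113.24, k_b = 1059.162 / 2,
                         k_a = 75.90 / 2, epsilon_OO = 0.1554253,
                         sigma_OO = 3.165492, k_e = 332.0637, r_cut = 5.5,
                         ewald_accuracy = 1e-6) {
  if (abs(q_O + 2 * q_H) > 1e-12)
    stop("SPC/FW molecule must be neutral: q_O + 2 q_H = 0")
  structure(list(q_O = q_O, q_H = q_H, r0 = r0, theta0 = theta0 * pi / 180,
                 k_b = k_b, k_a = k_a, epsilon_OO = epsilon_OO,
                 sigma_OO = sigma_OO, k_e = k_e, r_cut = r_cut,
                 ewald_accuracy = ewald_accuracy),
            class = "aq_spcfw_params")
}

spcfw_params_c <- function(p, cfg) {
  out <- list(kb = p$k_b, ka = p$k_a, r0 = p$r0, th0 = p$theta0,
              A = c(4 * p$epsilon_OO * p$sigma_OO^12, 0, 0),
              B = c(4 * p$epsilon_OO * p$sigma_OO^6, 0, 0),
              ke = p$k_e, qO = p$q_O, qH = p$q_H, rcut = p$r_cut,
              alpha = 0, kmax = c(1L, 1L, 1L))
  if (!is.null(cfg$cell)) {
    ew <- ewald_setup(cfg$cell, p$r_cut, p$ewald_accuracy)
    out$alpha <- ew$alpha
    out$kmax <- ew$kmax
  }
  out
}

#' SPC/FW energy and forces
#'
#' Harmonic intramolecular terms, 12-6 Lennard-Jones between oxygens, and
#' fixed-charge Coulomb (direct sum for clusters, Ewald for periodic cells);
#' intramolecular nonbonded interactions excluded.
#'
#' @param config a [configuration()].
#' @param params an [spcfw_params()].
#' @return list with the energy breakdown, `forces` and fixed `charges`.
#' @export
spcfw_energy_gradient <- function(config, params = spcfw_params()) {
  cc <- cfg_c(config)
  if (!is.null(config$cell)) check_cell_cutoff(config, params$r_cut)
  cpp_spcfw_eval(cc$pos, cc$elem, cc$mol, cc$molatoms, cc$cell,
                 spcfw_params_c(params, config))
}

#' Gas-phase monomer dipole of a fixed-charge 3-site model
#'
#' Closed form at the equilibrium geometry:
#' `mu = 2 |q_H| r0 cos(theta0/2)` in e*Angstrom, converted to Debye.
#'
#' @param params an [spcfw_params()].
#' @return dipole magnitude, Debye.
#' @export
spcfw_monomer_dipole <- function(params = spcfw_params()) {
  2 * abs(params$q_H) * params$r0 * cos(params$theta0 / 2) * .const$debye
}

#' Ideal single water molecule
#'
#' O at the origin with the HOH bisector along +x, lying in the xy plane.
#'
#' @param r0 bond length, A.
#' @param theta0 angle, degrees.
#' @param origin length-3 translation.
#' @return a [configuration()].
#' @export
water_monomer <- function(r0 = 1.012, theta0 = 113.24, origin = c(0, 0, 0)) {
  th <- theta0 * pi / 180
  pos <- rbind(c(0, 0, 0),
               r0 * c(cos(th / 2), sin(th / 2), 0),
               r0 * c(cos(th / 2), -sin(th / 2), 0))
  pos <- sweep(pos, 2, origin, "+")
  configuration(c("O", "H", "H"), pos)
}

#' Hydrogen-bonded water dimer starting geometry
#'
#' Donor molecule with one O-H bond pointing along +x at the acceptor's O;
#' a standard starting point for dimer optimization.
#'
#' @param r_OO initial O-O distance, A.
#' @param r0,theta0 monomer geometry.
#' @return a 2-molecule cluster [configuration()].
#' @export
water_dimer_start <- function(r_OO = 2.9, r0 = 1.012, theta0 = 113.24) {
  th <- theta0 * pi / 180
  # donor: O at origin, H1 along +x (the H bond), H2 off-axis
  don <- rbind(c(0, 0, 0),
               c(r0, 0, 0),
               r0 * c(cos(th), sin(th), 0))
  # acceptor: O on the +x axis, bisector pointing away tilted out of plane
  acc_o <- c(r_OO, 0, 0)
  tilt <- 50 * pi / 180
  bis <- c(cos(tilt), 0, sin(tilt))
  # orthonormal in-plane axis for the two H
  perp <- c(-sin(tilt), 0, cos(tilt))
  h1 <- acc_o + r0 * (cos(th / 2) * bis + sin(th / 2) * perp)
  h2 <- acc_o + r0 * (cos(th / 2) * bis - sin(th / 2) * perp)
  configuration(rep(c("O", "H", "H"), 2), rbind(don, acc_o, h1, h2))
}

# acceptor angle: angle between the acceptor HOH bisector and the O-O axis
dimer_acceptor_angle <- function(config, donor = 1L, acceptor = 2L) {
  ma <- config$molatoms
  oD <- config$positions[ma[donor, 1], ]
  oA <- config$positions[ma[acceptor, 1], ]
  bis <- (config$positions[ma[acceptor, 2], ] - oA) +
         (config$positions[ma[acceptor, 3], ] - oA)
  bis <- bis / sqrt(sum(bis^2))
  axis <- (oA - oD); axis <- axis / sqrt(sum(axis^2))
  # convention: angle of the bisector from the outward O-O direction
  acos(pmin(1, pmax(-1, sum(bis * axis)))) * 180 / pi
}

total_point_dipole <- function(config, q) {
  # neutral systems: origin-independent
  mu <- colSums(config$positions * as.numeric(q))
  sqrt(sum(mu^2)) * .const$debye
}

#' Optimize the water dimer and report its gas-phase properties
#'
#' Quasi-Newton minimization from a hydrogen-bonded start down to a maximum
#' force below `tol`.  The interaction energy `E_int` is the dimer energy
#' minus the energies of the two monomers evaluated at their in-dimer
#' geometries (the standard supermolecular interaction energy; monomer
#' deformation excluded).  The binding energy relative to relaxed monomers is
#' also reported as `E_bind`.  The acceptor angle `theta_A` is measured
#' between the acceptor molecule's HOH bisector and the O-O axis.
#'
#' @param params an [spcfw_params()] or [chargenn_model()]-compatible backend
#'   via `backend`.
#' @param start starting [configuration()]; default [water_dimer_start()].
#' @param backend optional energy backend (see [energy_backend()]); defaults
#'   to SPC/FW with `params`.
#' @param tol maximum-force convergence threshold, kcal/mol/A.
#' @return list of class `aq_dimer_report`: optimized `config`, `r_OO` (A),
#'   `theta_A` (deg), `E_int` (kcal/mol), `mu_total` (D), `converged`,
#'   `max_force`.
#' @export
optimize_dimer <- function(params = spcfw_params(), start = NULL,
                           backend = NULL, tol = 1e-6) {
  if (is.null(backend)) backend <- energy_backend("spcfw", params = params)
  if (is.null(start))
    start <- water_dimer_start(
      r0 = if (!is.null(params$r0)) params$r0 else 1.012,
      theta0 = if (!is.null(params$theta0)) params$theta0 * 180 / pi
               else 113.24)
  res <- minimize(start, backend, tol = tol)
  cfg <- res$config
  ev <- backend(cfg)
  # identify donor/acceptor: donor has the shortest intermolecular O-H contact
  ma <- cfg$molatoms
  dOH <- function(d, a) min(sqrt(rowSums((cfg$positions[ma[d, 2:3], ,
    drop = FALSE] - matrix(cfg$positions[ma[a, 1], ], 2, 3,
                           byrow = TRUE))^2)))
  donor <- if (dOH(1, 2) <= dOH(2, 1)) 1L else 2L
  acceptor <- 3L - donor
  rOO <- sqrt(sum((cfg$positions[ma[1, 1], ] - cfg$positions[ma[2, 1], ])^2))
  # monomer references at their in-dimer geometries
  Emono <- vapply(1:2, function(m) {
    idx <- ma[m, ]
    backend(configuration(cfg$species[idx],
                          cfg$positions[idx, , drop = FALSE],
                          mol = c(1L, 1L, 1L)))$U_total
  }, 0)
  structure(list(config = cfg, r_OO = rOO,
                 theta_A = dimer_acceptor_angle(cfg, donor, acceptor),
                 E_int = ev$U_total - sum(Emono),
                 E_bind = ev$U_total,
                 mu_total = total_point_dipole(cfg, ev$charges),
                 converged = res$converged, max_force = res$max_force,
                 donor = donor),
            class = "aq_dimer_report")
}

#' @export
print.aq_dimer_report <- function(x, ...) {
  cat(sprintf(paste0("water dimer minimum: r_OO = %.3f A, theta_A = %.1f deg, ",
                     "E_int = %.3f kcal/mol, mu = %.3f D (max|F| = %.2e)\n"),
              x$r_OO, x$theta_A, x$E_int, x$mu_total, x$max_force))
  invisible(x)
}
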