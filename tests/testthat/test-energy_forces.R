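test_that("intramolecular term follows the no-1/2 harmonic convention", {
  p <- ff_params(k_b = 500, k_a = 40)
  mono <- water_monomer(r0 = p$r_OH0, theta0 = p$theta0 * 180 / pi)
  ev <- intramolecular_energy(mono, p)
  expect_equal(ev$energy, 0, tolerance = 1e-20)
  expect_lt(max(abs(ev$gradient)), 1e-10)
  # stretch one bond by 0.1 A: U = k_b * 0.01
  stretched <- mono
  u <- (mono$positions[2, ] - mono$positions[1, ])
  u <- u / sqrt(sum(u^2))
  stretched$positions[2, ] <- stretched$positions[2, ] + 0.1 * u
  expect_equal(intramolecular_energy(stretched, p)$energy, 500 * 0.01,
               tolerance = 1e-10)
  # random distorted cluster: gradient vs finite differences
  set.seed(5)
  cl <- build_water_cluster(3, seed = 5)
  cl$positions <- cl$positions + matrix(rnorm(27, sd = 0.08), ncol = 3)
  num <- fd_forces(cl, function(c_) intramolecular_energy(c_, p)$energy)
  ana <- -intramolecular_energy(cl, p)$gradient   # forces
  expect_lt(max(abs(num - ana)) / max(abs(num)), 1e-6)
})

test_that("9-6 van der Waals has the analytic stationary point", {
  # A = B = 1: minimum at r = (3/2)^(1/3), U = -0.14815
  p <- ff_params(A_OO = 1, B_OO = 1)
  two <- function(r) configuration(
    rep(c("O", "H", "H"), 2),
    rbind(water_monomer()$positions,
          water_monomer(origin = c(r, 50, 0))$positions))
  # only the O-O pair carries 9-6 coefficients (H parameters default to 0)
  rmin <- (3 / 2)^(1 / 3)
  two_o <- function(r) configuration(c("O", "H", "H", "O", "H", "H"),
    rbind(c(0, 0, 0), c(0.6, 0.8, 0), c(0.6, -0.8, 0),
          c(r, 0, 0), c(r + 0.6, 0.8, 0), c(r + 0.6, -0.8, 0)),
    mol = rep(1:2, each = 3), check = FALSE)
  # hand sum over the single O-O pair
  uhand <- function(r) 1 / r^9 - 1 / r^6
  expect_equal(vdw_96_energy(two_o(2.0), p)$energy, uhand(2.0),
               tolerance = 1e-12)
  # minimum at r = (3/2)^(1/3) ~ 1.1447 with depth -4/27 ~ -0.1481
  expect_equal(vdw_96_energy(two_o(rmin), p)$energy, -4 / 27,
               tolerance = 1e-12)
  expect_equal(uhand(rmin), -4 / 27)
  # r -> infinity: zero
  expect_lt(abs(vdw_96_energy(two_o(80), p)$energy), 1e-11)
  # gradient zero at the stationary point
  g <- vdw_96_energy(two_o(rmin), p)$gradient
  expect_lt(max(abs(g)), 1e-10)
})

test_that("cluster Coulomb matches k_e and a naive double loop", {
  p <- ff_params()
  two <- configuration(c("O", "O"), rbind(c(0, 0, 0), c(1, 0, 0)),
                       mol = c(1, 2), check = FALSE)
  ev <- coulomb_cluster(two, c(1, 1), p)
  expect_equal(ev$energy, 332.0637)
  expect_equal(as.numeric(ev$phi), c(332.0637, 332.0637))
  expect_equal(coulomb_cluster(two, c(0, 0), p)$energy, 0)
  # 5-molecule cluster vs naive O(N^2) loop with intramolecular exclusion
  cl <- build_water_cluster(5, seed = 9)
  set.seed(10)
  q <- rnorm(15, sd = 0.4)
  ev <- coulomb_cluster(cl, q, p)
  ref <- 0
  for (i in 1:14) for (j in (i + 1):15) {
    if (cl$mol[i] == cl$mol[j]) next
    ref <- ref + p$k_e * q[i] * q[j] /
      sqrt(sum((cl$positions[i, ] - cl$positions[j, ])^2))
  }
  expect_equal(ev$energy, ref, tolerance = 1e-12)
})

test_that("Ewald reproduces the Madelung constant and is splitting-invariant", {
  # rock-salt +-1 lattice, spacing a = 2: energy per ion pair = -M k_e / a
  a <- 2; n <- 6
  g <- as.matrix(expand.grid(0:(n - 1), 0:(n - 1), 0:(n - 1)))
  cfg <- configuration(rep("O", nrow(g)), g * a, cell = rep(n * a, 3),
                       mol = seq_len(nrow(g)), check = FALSE)
  q <- (-1)^rowSums(g)
  p <- ff_params(k_e = 1, r_cut = 5.9)
  ew <- coulomb_ewald(cfg, q, p)
  per_pair <- 2 * ew$energy / nrow(g)
  expect_equal(per_pair, -1.747565 / a, tolerance = 1e-6)
  # doubling the splitting parameter leaves the energy unchanged
  alpha0 <- sqrt(-log(1e-6)) / p$r_cut
  ew2 <- coulomb_ewald(cfg, q, p, alpha = 2 * alpha0)
  expect_equal(ew2$energy, ew$energy, tolerance = 1e-6)
  # all-zero charges
  expect_equal(coulomb_ewald(cfg, rep(0, nrow(g)), p)$energy, 0)
  # water box: splitting invariance and agreement of phi with dU/dq by FD
  box <- make_box(seed = 3)
  set.seed(4)
  qs <- neutralize(rnorm(48, sd = 0.3))
  pw <- ff_params()
  e1 <- coulomb_ewald(box, qs, pw)
  e2 <- coulomb_ewald(box, qs, pw, alpha = 2 * sqrt(-log(1e-6)) / 5.5)
  expect_equal(e1$energy, e2$energy, tolerance = 1e-6)
  expect_error(coulomb_ewald(box, rep(0.1, 48), pw), "not neutral")
})

test_that("CT energy term is zero at zero, even, and peaks force at dq0", {
  p <- ff_params(k_c = 1.3, dq0 = 0.01)
  expect_equal(ct_energy(0, p)$energy, 0)
  x <- seq(-0.05, 0.05, by = 1e-4)
  ue <- vapply(x, function(v) ct_energy(v, p)$energy, 0)
  expect_equal(ue, rev(ue))                       # even
  expect_true(all(ue <= 0 & ue > -p$k_c))        # bounded below by -k_c
  # |dU/ddq| maximal at dq = dq0 by numeric scan
  du <- abs(vapply(x, function(v) ct_energy(v, p)$dU_ddq, 0))
  expect_equal(abs(x[which.max(du)]), p$dq0, tolerance = 2e-4)
})

test_that("full-model analytic forces match finite differences (clusters)", {
  model <- make_random_model(5)
  worst <- 0
  for (s in 1:6) {
    nmol <- sample(2:6, 1)
    cfg <- build_water_cluster(nmol, seed = 40 + s)
    ev <- total_energy_and_gradient(cfg, model)
    expect_equal(ev$U_total, ev$U_intra + ev$U_vdw + ev$U_coul + ev$U_ct)
    num <- fd_forces(cfg, function(c_)
      total_energy_and_gradient(c_, model, forces = FALSE)$U_total)
    worst <- max(worst, max(abs(num - ev$forces)) / max(abs(num)))
  }
  expect_lt(worst, 1e-5)
})

test_that("full-model analytic forces match finite differences (periodic)", {
  model <- make_random_model(6)
  box <- make_box(seed = 7)
  ev <- total_energy_and_gradient(box, model)
  num <- fd_forces(box, function(c_)
    total_energy_and_gradient(c_, model, forces = FALSE)$U_total)
  expect_lt(max(abs(num - ev$forces)) / max(abs(num)), 1e-5)
})

test_that("cluster forces sum to zero with zero net torque", {
  model <- make_random_model(8)
  cfg <- build_water_cluster(5, seed = 13)
  ev <- total_energy_and_gradient(cfg, model)
  expect_lt(max(abs(colSums(ev$forces))), 1e-8)
  torque <- colSums(cbind(
    cfg$positions[, 2] * ev$forces[, 3] - cfg$positions[, 3] * ev$forces[, 2],
    cfg$positions[, 3] * ev$forces[, 1] - cfg$positions[, 1] * ev$forces[, 3],
    cfg$positions[, 1] * ev$forces[, 2] - cfg$positions[, 2] * ev$forces[, 1]))
  expect_lt(max(abs(torque)), 1e-7)
  # energy invariant under rigid motions
  U0 <- ev$U_total
  for (s in 1:5)
    expect_equal(total_energy_and_gradient(rigid_motion(cfg, s), model,
                                           forces = FALSE)$U_total, U0,
                 tolerance = 1e-9)
})

test_that("energy is invariant under lattice translations", {
  model <- make_random_model(9)
  box <- make_box(seed = 11)
  U0 <- total_energy_and_gradient(box, model, forces = FALSE)$U_total
  shifted <- box
  shifted$positions <- shifted$positions +
    matrix(box$cell, nrow(box$positions), 3, byrow = TRUE)
  expect_equal(total_energy_and_gradient(shifted, model,
                                         forces = FALSE)$U_total, U0,
               tolerance = 1e-8)
  wrapped <- wrap_molecules(box)
  expect_equal(total_energy_and_gradient(wrapped, model,
                                         forces = FALSE)$U_total, U0,
               tolerance = 1e-8)
})

test_that("energy is continuous as a pair crosses the CT cutoff", {
  model <- make_random_model(10)
  spec <- model$spec
  U_at <- function(r) {
    d <- water_dimer_start(r_OO = r)
    total_energy_and_gradient(d, model, forces = FALSE)$U_total
  }
  # centered second difference cancels the smooth slope; a discontinuity
  # would survive at its full size
  eps <- 1e-6
  for (rc in c(spec$ct_cutoff, spec$r_c)) {
    jump <- abs(U_at(rc + eps) + U_at(rc - eps) - 2 * U_at(rc))
    expect_lt(jump, 1e-9)
  }
})
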