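test_that("ideal-gas frames give g(r) = 1 and lattice frames give peaks", {
  set.seed(21)
  L <- 12
  frames <- lapply(1:40, function(k)
    configuration(rep("O", 60), matrix(runif(180, 0, L), ncol = 3),
                  cell = rep(L, 3), mol = 1:60, check = FALSE))
  g <- radial_distribution(frames, c("O", "O"), dr = 0.25)
  sel <- g$r > 2 & g$r < 5.5
  expect_lt(abs(mean(g$g[sel]) - 1), 0.05)
  # simple cubic lattice: sharp peaks at a, a*sqrt(2), ...
  a <- 3
  gr <- as.matrix(expand.grid(0:3, 0:3, 0:3)) * a
  lat <- configuration(rep("O", nrow(gr)), gr, cell = rep(12, 3),
                       mol = seq_len(nrow(gr)), check = FALSE)
  gl <- radial_distribution(list(lat), c("O", "O"), dr = 0.1)
  peak_r <- gl$r[gl$g > 10]
  expect_true(any(abs(peak_r - a) < 0.1))
  expect_true(any(abs(peak_r - a * sqrt(2)) < 0.1))
  expect_true(all(gl$g[gl$r < 2.9] == 0))
  expect_error(radial_distribution(frames, r_max = 7), "half the smallest")
})

test_that("molecular dipoles use the nuclear charge center convention", {
  p <- spcfw_params()
  mono <- water_monomer(r0 = p$r0, theta0 = p$theta0 * 180 / pi)
  md <- molecular_dipole(mono, c(-0.82, 0.41, 0.41))
  expect_equal(md$mu, 2.19, tolerance = 0.005)
  expect_equal(md$q_mol, 0)
  # neutral molecule: dipole independent of a global origin shift
  shifted <- mono
  shifted$positions <- shifted$positions + 5
  expect_equal(molecular_dipole(shifted, c(-0.82, 0.41, 0.41))$mu, md$mu)
  # charged molecule: origin dependence equals q_net x origin shift
  qc <- c(-0.7, 0.41, 0.41)  # net +0.12 e
  m1 <- molecular_dipole(mono, qc)
  m2 <- molecular_dipole(shifted, qc)
  expect_equal(m1$mu, m2$mu, tolerance = 1e-10)  # origin moves with molecule
})

test_that("IR spectrum recovers tone frequencies", {
  dt <- 1                      # fs
  t <- (0:4095) * dt
  nu1 <- 1000 / 33356.40952    # 1000 1/cm as cycles/fs
  nu2 <- 2500 / 33356.40952
  sig1 <- cos(2 * pi * nu1 * t)
  sp1 <- ir_spectrum(sig1, dt, correction = "none")
  expect_equal(sp1$nu[which.max(sp1$intensity)], 1000, tolerance = 20)
  two <- cos(2 * pi * nu1 * t) + 0.7 * cos(2 * pi * nu2 * t)
  sp2 <- ir_spectrum(two, dt, correction = "none")
  ord <- order(-sp2$intensity)
  top2 <- sort(sp2$nu[ord[1:2]])
  expect_equal(top2, c(1000, 2500), tolerance = 25)
  # white noise: approximately flat spectrum (no dominant single peak)
  set.seed(3)
  spw <- ir_spectrum(rnorm(4096), dt, correction = "none")
  band <- spw$intensity[spw$nu > 200 & spw$nu < 4000]
  expect_lt(max(band) / mean(band), 12)
})

test_that("self-diffusion recovers a known Brownian coefficient", {
  # synthetic Brownian walk: D in A^2/fs, MSD = 6 D t
  set.seed(7)
  D_true <- 2.3e-4                      # A^2/fs = 2.3 in 1e-5 cm^2/s units
  dt <- 10                              # fs between frames
  n <- 600; natoms <- 30
  steps <- array(rnorm(natoms * 3 * n, sd = sqrt(2 * D_true * dt)),
                 c(natoms, 3, n))
  pos <- aperm(apply(steps, c(1, 2), cumsum), c(2, 3, 1))
  frames <- lapply(1:n, function(k)
    configuration(rep("O", natoms), pos[, , k], mol = 1:natoms,
                  check = FALSE))
  est <- self_diffusion(frames, dt_fs = dt)
  expect_equal(est$D, D_true * 1e4, tolerance = 0.05 * D_true * 1e4)
  # frozen trajectory: zero
  frozen <- lapply(1:50, function(k) frames[[1]])
  expect_lt(abs(self_diffusion(frozen, dt_fs = dt)$D), 1e-12)
})

test_that("tetrahedral order is 1 for a tetrahedron and negative when collinear", {
  tet <- rbind(c(0, 0, 0),
               c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  cfg <- configuration(rep("O", 5), tet, mol = 1:5, check = FALSE)
  q <- tetrahedral_order(cfg)
  expect_equal(q$q[1], 1, tolerance = 1e-12)
  # random neighbor directions: mean near zero (Monte-Carlo oracle)
  set.seed(9)
  vals <- replicate(400, {
    u <- matrix(rnorm(12), 4, 3)
    u <- u / sqrt(rowSums(u^2))
    s <- 0
    for (j in 1:3) for (k in (j + 1):4)
      s <- s + (sum(u[j, ] * u[k, ]) + 1 / 3)^2
    1 - 3 / 8 * s
  })
  expect_lt(abs(mean(vals)), 0.05)
  # collinear neighbors: strongly negative
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(-1, 0, 0), c(-2, 0, 0))
  cc <- configuration(rep("O", 5), col, mol = 1:5, check = FALSE)
  expect_lt(tetrahedral_order(cc)$q[1], 0)
  # too few neighbors are excluded and counted
  small <- configuration(rep("O", 3), diag(3), mol = 1:3, check = FALSE)
  expect_equal(tetrahedral_order(small)$n_excluded, 3)
})

test_that("heat of vaporization arithmetic matches the ideal-gas relation", {
  expect_equal(heat_of_vaporization(0, 298.15), 0.0019872041 * 298.15)
  expect_equal(heat_of_vaporization(-5, 0), 5)
  expect_equal(heat_of_vaporization(-9.917, 298.15), 10.51, tolerance = 0.005)
})

test_that("layer statistics match hand-computed shells and conserve charge", {
  # three molecules at known radii from the center of mass, assigned charges
  m1 <- water_monomer(origin = c(0, 0, 0))
  m2 <- water_monomer(origin = c(2.5, 0, 0))
  m3 <- water_monomer(origin = c(-2.5, 0, 0))
  cfg <- configuration(rep(c("O", "H", "H"), 3),
                       rbind(m1$positions, m2$positions, m3$positions))
  q <- c(-0.1, 0.04, 0.06, -0.2, 0.1, 0.1, 0.3, -0.15, -0.15)
  ls <- layer_statistics(list(cfg), shell_width = 1.5, charges = list(q),
                         r_max = 4.5)
  # whole-droplet hydrogen proportion is exactly 2/3
  expect_equal(ls$pha_total, 200 / 3, tolerance = 1e-10)
  # sum over shells of VCD x exact shell volume returns the total charge
  vol <- 4 / 3 * pi * (ls$shells$r_hi^3 - ls$shells$r_lo^3) / 1000
  got <- sum(ls$shells$vcd * vol, na.rm = TRUE)
  expect_equal(got, sum(q), tolerance = 1e-10)
  expect_equal(ls$total_charge, sum(q), tolerance = 1e-12)
  # uniform neutral droplet: zero VCD in every occupied shell
  q0 <- rep(0, 9)
  ls0 <- layer_statistics(list(cfg), shell_width = 1.5, charges = list(q0),
                          r_max = 4.5)
  occ <- !is.na(ls0$shells$vcd)
  expect_true(all(ls0$shells$vcd[occ] == 0))
})
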