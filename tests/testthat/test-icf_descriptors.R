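test_that("cutoff weight has the stated closed form and smooth end", {
  expect_equal(cutoff_weight(0, 4.4), 1)
  expect_equal(cutoff_weight(4.4, 4.4), 0)
  expect_equal(cutoff_weight(2.2, 4.4), 0.5)
  expect_equal(cutoff_weight(5.0, 4.4), 0)
  # derivative vanishes at the cutoff
  h <- 1e-6
  expect_lt(abs(cutoff_weight(4.4 - h, 4.4) / h), 1e-5)
  expect_error(cutoff_weight(1, -1), "positive")
})

test_that("single ICF values match the closed form and the naive oracle", {
  # one neighbor at r = 2, k_f = 1: e^-2 * (cos(2 pi / 4.4) + 1) / 2
  cfg <- configuration(c("O", "O"), rbind(c(0, 0, 0), c(2, 0, 0)),
                       mol = c(1, 2), check = FALSE)
  expect_equal(icf_value(cfg, 1, "O", "inter", k_f = 1, r_c = 4.4),
               exp(-2) * 0.5 * (cos(2 * pi / 4.4) + 1))
  # isolated atom: no neighbors in class
  expect_equal(icf_value(cfg, 1, "H", "inter", k_f = 1, r_c = 4.4), 0)
  expect_equal(icf_value(cfg, 1, "O", "intra", k_f = 1, r_c = 4.4), 0)
  # permuting identical neighbors leaves the sum unchanged
  c3 <- configuration(c("O", "O", "O"),
                      rbind(c(0, 0, 0), c(2, 0, 0), c(0, 3, 0)),
                      mol = 1:3, check = FALSE)
  c3p <- c3; c3p$positions[2:3, ] <- c3$positions[3:2, ]
  expect_equal(icf_value(c3, 1, "O", "inter", 1, 4.4),
               icf_value(c3p, 1, "O", "inter", 1, 4.4))
  # random dimer: every atom/class/scope combination vs the naive R loop
  set.seed(3)
  d <- water_dimer_start()
  d$positions <- d$positions + matrix(rnorm(18, sd = 0.1), ncol = 3)
  for (ctr in 1:6) for (cl in c("O", "H")) for (sc in c("intra", "inter"))
    expect_equal(icf_value(d, ctr, cl, sc, 1.3, 4.4),
                 naive_icf(d, ctr, cl, sc, 1.3, 4.4), tolerance = 1e-12)
})

test_that("charge feature vectors have the documented layout and content", {
  spec <- icf_spec()
  mono <- water_monomer()
  F <- charge_feature_vector(mono, spec)
  expect_equal(dim(F), c(3, 24))
  # isolated monomer: all intermolecular slots zero, intra slots positive
  inter_cols <- grepl("inter|sib", colnames(F))
  expect_true(all(F[, inter_cols] == 0))
  expect_true(all(F[2, grepl("intra", colnames(F))] > 0))  # H centre
  # O centre has no intra-O partner
  expect_true(all(F[1, grepl("intra.O", colnames(F), fixed = TRUE)] == 0))
  # dimer slots vs naive double loop
  set.seed(5)
  d <- water_dimer_start()
  Fd <- unname(charge_feature_vector(d, spec))
  for (t in 1:3) {
    kf <- spec$k_f[t]
    for (a in 1:6) {
      expect_equal(Fd[a, 8 * t - 7], naive_icf(d, a, "O", "intra", kf, 4.4))
      expect_equal(Fd[a, 8 * t - 6], naive_icf(d, a, "H", "intra", kf, 4.4))
      expect_equal(Fd[a, 8 * t - 5], naive_icf(d, a, "O", "inter", kf, 4.4))
      expect_equal(Fd[a, 8 * t - 4], naive_icf(d, a, "H", "inter", kf, 4.4))
    }
    # H-centre sibling blocks: O sibling then other H, raw values
    expect_equal(Fd[2, 8 * t - 3], naive_icf(d, 1, "O", "inter", kf, 4.4))
    expect_equal(Fd[2, 8 * t - 1], naive_icf(d, 3, "O", "inter", kf, 4.4))
    # O-centre sibling blocks: power sums over the two H
    h1 <- naive_icf(d, 2, "O", "inter", kf, 4.4)
    h2 <- naive_icf(d, 3, "O", "inter", kf, 4.4)
    expect_equal(Fd[1, 8 * t - 3], h1 + h2)
    expect_equal(Fd[1, 8 * t - 1], h1^2 + h2^2)
  }
})

test_that("features are invariant under rigid motions and H relabeling", {
  spec <- icf_spec()
  set.seed(8)
  cfg <- build_water_cluster(5, seed = 8)
  F0 <- charge_feature_vector(cfg, spec)
  for (s in 1:25) {
    Fm <- charge_feature_vector(rigid_motion(cfg, s), spec)
    expect_lt(max(abs(Fm - F0)), 1e-12)
  }
  # swapping the H labels of a molecule permutes atom rows but leaves every
  # atom's feature vector unchanged
  swp <- cfg
  ma <- cfg$molatoms
  swp$positions[ma[2, 2:3], ] <- cfg$positions[ma[2, 3:2], ]
  Fs <- charge_feature_vector(swp, spec)
  expect_lt(max(abs(Fs[ma[1, ], ] - F0[ma[1, ], ])), 1e-12)   # other molecule
  expect_lt(max(abs(Fs[ma[2, 1], ] - F0[ma[2, 1], ])), 1e-12) # O of swapped
  expect_lt(max(abs(Fs[ma[2, 2], ] - F0[ma[2, 3], ])), 1e-12) # H swapped rows
})

test_that("adding an atom beyond every cutoff changes no feature (locality)", {
  spec <- icf_spec()
  cfg <- build_water_cluster(3, seed = 2)
  F0 <- charge_feature_vector(cfg, spec)
  far <- water_monomer(origin = c(60, 0, 0))
  big <- configuration(c(cfg$species, far$species),
                       rbind(cfg$positions, far$positions))
  F1 <- charge_feature_vector(big, spec)
  expect_equal(F1[seq_len(nrow(F0)), ], F0, ignore_attr = TRUE)
})

test_that("CT features follow the pair layout and swap blockwise", {
  spec <- icf_spec()
  # two monomers 10 A apart: no CT pair
  far <- configuration(rep(c("O", "H", "H"), 2),
                       rbind(water_monomer()$positions,
                             water_monomer(origin = c(10, 0, 0))$positions))
  expect_null(ct_feature_vector(far, 1, 2, spec))
  # hydrogen-bonded dimer: matches a naive loop restricted to the partner
  d <- water_dimer_start(r_OO = 2.8)
  F12 <- ct_feature_vector(d, 1, 2, spec)
  F21 <- ct_feature_vector(d, 2, 1, spec)
  expect_equal(F21, c(F12[19:36], F12[1:18]))
  naive_h <- function(a, partner_atoms, class, kf) {
    tot <- 0
    for (b in partner_atoms) {
      if (d$species[b] != class) next
      r <- sqrt(sum((d$positions[b, ] - d$positions[a, ])^2))
      if (r < spec$ct_cutoff)
        tot <- tot + exp(-kf * r) * 0.5 * (cos(pi * r / spec$ct_cutoff) + 1)
    }
    tot
  }
  for (t in 1:3) {
    kf <- spec$k_f[t]
    # O atom of I against J, classes O and H
    expect_equal(F12[6 * t - 5], naive_h(1, 4:6, "O", kf))
    expect_equal(F12[6 * t - 4], naive_h(1, 4:6, "H", kf))
    h1 <- naive_h(2, 4:6, "O", kf); h2 <- naive_h(3, 4:6, "O", kf)
    expect_equal(F12[6 * t - 3], h1 + h2)
    expect_equal(F12[6 * t - 1], h1^2 + h2^2)
    # J half against I
    expect_equal(F12[18 + 6 * t - 5], naive_h(4, 1:3, "O", kf))
  }
})

test_that("analytic feature Jacobians match finite differences", {
  spec <- icf_spec()
  set.seed(12)
  cfg <- build_water_cluster(5, seed = 12)
  h <- 1e-5
  fd_jac <- function(getF) {
    F0 <- getF(cfg)
    J <- matrix(0, length(F0), 3 * nrow(cfg$positions))
    for (a in seq_len(nrow(cfg$positions))) for (c in 1:3) {
      cp <- cfg; cp$positions[a, c] <- cp$positions[a, c] + h
      cm <- cfg; cm$positions[a, c] <- cm$positions[a, c] - h
      J[, 3 * (a - 1) + c] <- (getF(cp) - getF(cm)) / (2 * h)
    }
    J
  }
  for (atom in c(1, 5, 9)) {
    Ja <- feature_jacobian(cfg, atom, spec)
    Jn <- fd_jac(function(c_) charge_feature_vector(c_, spec)[atom, ])
    expect_lt(max(abs(Ja - Jn)) / max(abs(Jn)), 1e-6)
  }
  # CT pair Jacobian (choose a pair within the cutoff by O-O distance)
  oidx <- cfg$molatoms[, 1]
  d12 <- as.matrix(dist(cfg$positions[oidx, ]))
  pr <- which(d12 < spec$ct_cutoff & upper.tri(d12), arr.ind = TRUE)[1, ]
  pair <- c(pr[1], pr[2])
  Jc <- feature_jacobian(cfg, pair, spec)
  Jn <- fd_jac(function(c_) ct_feature_vector(c_, pair[1], pair[2], spec))
  expect_lt(max(abs(Jc - Jn)) / max(abs(Jn)), 1e-6)
  # atom with no neighbors: zero Jacobian rows beyond its own molecule
  mono <- water_monomer()
  Jm <- feature_jacobian(mono, 1, spec)
  expect_equal(dim(Jm), c(24, 9))
})

test_that("features vanish smoothly as a neighbor crosses the cutoff", {
  spec <- icf_spec()
  val_at <- function(r) {
    cfg <- configuration(c("O", "O"), rbind(c(0, 0, 0), c(r, 0, 0)),
                         mol = c(1, 2), check = FALSE)
    icf_value(cfg, 1, "O", "inter", 1, spec$r_c)
  }
  eps <- 1e-6
  expect_lt(abs(val_at(spec$r_c - eps)), 1e-11)   # value -> 0
  expect_lt(abs(val_at(spec$r_c - eps) - val_at(spec$r_c - 2 * eps)), 1e-11)
  expect_identical(val_at(spec$r_c + eps), 0)
})
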