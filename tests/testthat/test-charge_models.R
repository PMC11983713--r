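test_that("swish matches its closed form and asymptotes", {
  expect_equal(swish(0), 0)
  expect_equal(swish(1, beta = 3), 1 / (1 + exp(-3)))
  expect_equal(swish(50, beta = 3) / 50, 1, tolerance = 1e-10)
  expect_equal(swish(c(-1, 0, 2), 1), c(-1, 0, 2) / (1 + exp(c(1, 0, -2))))
})

test_that("network forward pass is deterministic and hand-checkable", {
  # zero weights: zero output for any input
  n0 <- dense_network(4, c(3, 3, 3, 3), init = 0)
  expect_equal(forward_charge(n0, matrix(rnorm(20), 5, 4)), rep(0, 5))
  # single-path network with hand-set weights: composition of swishes
  n1 <- dense_network(1, c(1, 1, 1, 1), init = 0)
  for (l in 1:5) n1$W[[l]] <- matrix(1, 1, 1)
  n1$b <- lapply(n1$b, function(b) b + 0.2)
  x <- 0.7
  z <- x
  for (l in 1:4) z <- swish(z + 0.2, 3)
  expect_equal(forward_charge(n1, x), z + 0.2)
  # determinism
  nr <- dense_network(24, seed = 3)
  X <- matrix(rnorm(48), 2, 24)
  expect_identical(forward_charge(nr, X), forward_charge(nr, X))
  expect_error(forward_charge(nr, matrix(0, 1, 10)), "width")
})

test_that("input gradients agree with finite differences and linear oracle", {
  # random networks vs central finite differences
  for (s in 1:6) {
    net <- dense_network(6, c(5, 5, 5, 5), seed = s)
    net$x_center <- rnorm(6, sd = 0.1); net$x_scale <- runif(6, 0.5, 2)
    net$y_scale <- 0.3; net$y_center <- -0.1
    set.seed(100 + s)
    x <- rnorm(6)
    g <- charge_input_gradient(net, x)
    h <- 1e-6
    gn <- vapply(1:6, function(k) {
      xp <- x; xp[k] <- xp[k] + h
      xm <- x; xm[k] <- xm[k] - h
      (forward_charge(net, xp) - forward_charge(net, xm)) / (2 * h)
    }, 0)
    expect_lt(max(abs(g - gn)) / max(abs(gn)), 1e-6)
  }
  # zero-weight network: zero gradient
  n0 <- dense_network(6, c(5, 5, 5, 5), init = 0)
  expect_equal(as.numeric(charge_input_gradient(n0, rnorm(6))), rep(0, 6))
  # deep in the positive linear regime, gradient = product of weight rows
  nl <- dense_network(3, c(2, 2, 2, 2), seed = 2)
  for (l in seq_along(nl$W)) nl$W[[l]] <- abs(nl$W[[l]])
  nl$b <- lapply(nl$b, function(b) b + 50)  # large positive pre-activations
  g <- as.numeric(charge_input_gradient(nl, c(1, 1, 1)))
  prod_ <- nl$W[[5]] %*% nl$W[[4]] %*% nl$W[[3]] %*% nl$W[[2]] %*% nl$W[[1]]
  expect_equal(g, as.numeric(prod_), tolerance = 1e-6)
})

test_that("neutralization removes the mean and records the shift", {
  n <- neutralize(c(0.1, 0.2, 0.3))
  expect_equal(n$dq_shift, 0.2)
  expect_equal(n$q, c(-0.1, 0, 0.1))
  already <- neutralize(c(-0.5, 0.25, 0.25))
  expect_equal(already$dq_shift, 0)
  set.seed(4)
  r <- neutralize(rnorm(37))
  expect_lt(abs(sum(r$q)), 1e-12)
})

test_that("pair CT is antisymmetric, gated at the cutoff, zero far away", {
  spec <- icf_spec()
  net <- dense_network(36, c(8, 8, 8, 8), seed = 7)
  far <- configuration(rep(c("O", "H", "H"), 2),
                       rbind(water_monomer()$positions,
                             water_monomer(origin = c(10, 0, 0))$positions))
  expect_equal(predict_pair_ct(net, far, 1, 2, spec), 0)
  d <- water_dimer_start(r_OO = 2.8)
  dq <- predict_pair_ct(net, d, 1, 2, spec)
  expect_equal(predict_pair_ct(net, d, 2, 1, spec), -dq)
  expect_true(dq != 0)
  # approaching the cutoff the value goes to zero continuously
  near <- water_dimer_start(r_OO = spec$ct_cutoff - 1e-5)
  expect_lt(abs(predict_pair_ct(net, near, 1, 2, spec)), 1e-7)
})

test_that("CM5 mapping preserves total charge and matches hand evaluation", {
  p <- cm5_params()
  # homonuclear pair: T = 0 for identical elements, CM5 = Hirshfeld
  o2 <- configuration(c("O", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
                      mol = c(1, 2), check = FALSE)
  expect_equal(cm5_from_hirshfeld(c(0.1, -0.1), o2, p), c(0.1, -0.1))
  # water monomer at the experimental geometry, typical Hirshfeld charges:
  # hand evaluation of the pairwise exponential correction
  mono <- water_monomer(r0 = 0.9572, theta0 = 104.52)
  hpa <- c(-0.312, 0.156, 0.156)
  q <- cm5_from_hirshfeld(hpa, mono, p)
  rOH <- 0.9572
  rHH <- sqrt(sum((mono$positions[2, ] - mono$positions[3, ])^2))
  bOH <- exp(-p$alpha * (rOH - p$radii[["H"]] - p$radii[["O"]]))
  expect_equal(q[2], hpa[2] + p$T_HO * bOH)
  expect_equal(q[1], hpa[1] - 2 * p$T_HO * bOH)
  # total charge conserved exactly (antisymmetry of the pair coefficients)
  expect_equal(sum(q), sum(hpa), tolerance = 1e-14)
  # H becomes more positive than Hirshfeld (known CM5 behavior for water)
  expect_gt(q[2], hpa[2])
  expect_error(cm5_from_hirshfeld(c(0, 0), o2, cm5_params(radii = c(H = 1))),
               "no CM5 parameters")
})

test_that("predicted charges are rigid-motion invariant and neutral", {
  model <- make_random_model(3)
  nets <- list(O = model$net_O, H = model$net_H)
  cfg <- build_water_cluster(4, seed = 6)
  q0 <- predict_charges(cfg, nets)
  expect_lt(abs(sum(q0$q)), 1e-12)
  for (s in 1:5) {
    qm <- predict_charges(rigid_motion(cfg, s), nets)
    expect_lt(max(abs(qm$q - q0$q)), 1e-10)
  }
})

test_that("weight archives round-trip bit for bit", {
  net <- dense_network(24, seed = 9)
  net$x_center <- rnorm(24); net$x_scale <- runif(24, 0.5, 2)
  net$y_center <- pi / 7; net$y_scale <- exp(1) / 911
  f <- tempfile(fileext = ".json")
  save_network(net, f, layout = "charge-icf-24")
  back <- load_network(f)
  expect_identical(back$W, net$W)
  expect_identical(back$b, net$b)
  expect_identical(back$x_center, net$x_center)
  expect_identical(back$x_scale, net$x_scale)
  expect_identical(back$y_center, net$y_center)
  expect_identical(back$y_scale, net$y_scale)
  expect_identical(attr(back, "layout"), "charge-icf-24")
  unlink(f)
})

test_that("a small training run learns a linear surrogate map", {
  # quick sanity on the optimizer itself (the full learnability property is
  # exercised in the acceptance suite)
  set.seed(20)
  X <- matrix(rnorm(400 * 6), 400, 6)
  y <- 0.3 * X[, 1] - 0.2 * X[, 4] + 0.05
  net <- dense_network(6, c(8, 8, 8, 8), seed = 1)
  net <- train_network(net, X[1:300, ], y[1:300], X[301:350, ], y[301:350],
                       epochs = 120, batch = 64, lr = 3e-3, seed = 2)
  pred <- forward_charge(net, X[351:400, ])
  expect_lt(mean(abs(pred - y[351:400])), 0.1 * sd(y))
})
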