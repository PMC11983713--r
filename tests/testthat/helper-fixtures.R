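# fixtures and independent oracles shared across the suite; everything is
# built in code at test time

# periodic 16-molecule box (gas-density: minimum-image validity requires
# L > 2 x the largest cutoff)
make_box <- function(n = 16, L = 11.2, seed = 4) {
  set.seed(seed)
  k <- ceiling(n^(1 / 3))
  grid <- as.matrix(expand.grid(seq_len(k), seq_len(k),
                                seq_len(k)))[seq_len(n), ] * (L / k) - 1.8
  pos <- NULL; sp <- character(0)
  for (m in seq_len(n)) {
    mono <- water_monomer()
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    p <- mono$positions %*% t(R)
    p <- sweep(p, 2, grid[m, ] + runif(3, -0.3, 0.3), "+")
    pos <- rbind(pos, p); sp <- c(sp, mono$species)
  }
  configuration(sp, pos, cell = c(L, L, L))
}

# random-weight model with charge-like output scales (for gradient tests)
make_random_model <- function(seed = 5, hidden = c(8, 8, 8, 8), ...) {
  nO <- dense_network(24, hidden, seed = seed, init = 0.7)
  nH <- dense_network(24, hidden, seed = seed + 1, init = 0.7)
  nC <- dense_network(36, hidden, seed = seed + 2, init = 0.7)
  nO$y_center <- -0.8; nO$y_scale <- 0.1
  nH$y_center <- 0.4;  nH$y_scale <- 0.05
  nC$y_center <- 0;    nC$y_scale <- 0.01
  chargenn_model(nO, nH, nC, ...)
}

# constant-output model (fixed charges through the dynamic-charge path)
make_const_model <- function(qO = -0.82, qH = 0.41, ...) {
  cn <- function(n_in, y) {
    n <- dense_network(n_in, c(8, 8, 8, 8), init = 0)
    n$y_center <- y
    n
  }
  chargenn_model(cn(24, qO), cn(24, qH), cn(36, 0), ...)
}

# central finite-difference forces for any energy closure
fd_forces <- function(cfg, energy_fn, h = 1e-5) {
  num <- matrix(0, nrow(cfg$positions), 3)
  for (i in seq_len(nrow(cfg$positions))) for (c in 1:3) {
    cp <- cfg; cp$positions[i, c] <- cp$positions[i, c] + h
    cm <- cfg; cm$positions[i, c] <- cm$positions[i, c] - h
    num[i, c] <- -(energy_fn(cp) - energy_fn(cm)) / (2 * h)
  }
  num
}

# independent naive ICF: explicit double loop in R
naive_icf <- function(cfg, center, class, scope, k_f, r_c) {
  tot <- 0
  for (j in seq_len(nrow(cfg$positions))) {
    if (j == center || cfg$species[j] != class) next
    same <- cfg$mol[j] == cfg$mol[center]
    if ((scope == "intra") != same) next
    d <- cfg$positions[j, ] - cfg$positions[center, ]
    if (!is.null(cfg$cell)) d <- d - cfg$cell * round(d / cfg$cell)
    r <- sqrt(sum(d^2))
    if (r < r_c) tot <- tot + exp(-k_f * r) * 0.5 * (cos(pi * r / r_c) + 1)
  }
  tot
}

# random rigid motion applied to a configuration (cluster)
rigid_motion <- function(cfg, seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t_ <- rnorm(3, sd = 5)
  cfg$positions <- sweep(cfg$positions %*% t(R), 2, t_, "+")
  cfg
}

# memoized heavy artefacts shared by the acceptance tests
.acc_env <- new.env(parent = emptyenv())

acceptance_dataset <- function() {
  if (is.null(.acc_env$ds)) {
    .acc_env$ds <- make_training_set(
      500, 25, surrogate_params(sigma_noise = 0), seed = 11L)
  }
  .acc_env$ds
}

acceptance_trained <- function() {
  if (is.null(.acc_env$trained)) {
    .acc_env$trained <- train_charge_model(
      acceptance_dataset(), epochs = 150, batch = 512, lr = 2e-3, seed = 11L)
  }
  .acc_env$trained
}

acceptance_model <- function() {
  tr <- acceptance_trained()
  chargenn_model(tr$net_O, tr$net_H, tr$net_CT)
}

# linear-fit total-energy drift of an NVE trajectory, relative to |E(0)|
nve_drift <- function(traj) {
  E <- traj$energy$U_total + traj$energy$KE
  t <- traj$energy$time
  fit <- lm(E ~ t)
  abs(coef(fit)[2]) * diff(range(t)) / abs(E[1])
}
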