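#' Energy backends
#'
#' A backend is a function `config -> list(U_total, forces, U_intra, U_vdw,
#' U_coul, U_ct, charges, ...)` used by the MD engine and the minimizer.  Two
#' are provided: the dynamic-charge neural-network model and the fixed-charge
#' SPC/FW baseline.
#'
#' @param model `"chargenn"` or `"spcfw"`.
#' @param nn an [chargenn_model()] (required for `"chargenn"`).
#' @param params an [spcfw_params()] (for `"spcfw"`).
#' @return a backend closure of class `aq_backend`.
#' @export
energy_backend <- function(model = c("chargenn", "spcfw"), nn = NULL,
                           params = spcfw_params()) {
  model <- match.arg(model)
  f <- if (model == "chargenn") {
    stopifnot(inherits(nn, "aq_model"))
    function(config) total_energy_and_gradient(config, nn)
  } else {
    function(config) spcfw_energy_gradient(config, params)
  }
  structure(f, class = c("aq_backend", "function"), model = model)
}

atom_masses <- function(config) {
  ifelse(config$species == "O", .const$mass_O, .const$mass_H)
}

#' Maxwell-Boltzmann velocities
#'
#' @param config a [configuration()].
#' @param T_K temperature, K.
#' @param seed integer seed.
#' @param remove_com remove the center-of-mass drift.
#' @return the configuration with velocities set (Angstrom/fs).
#' @export
init_velocities <- function(config, T_K, seed, remove_com = TRUE) {
  set.seed(seed)
  m <- atom_masses(config)
  sdv <- sqrt(.const$kB * T_K / m * .const$acc)  # A/fs
  v <- matrix(rnorm(3 * length(m)), ncol = 3) * sdv
  if (remove_com) {
    vc <- colSums(v * m) / sum(m)
    v <- sweep(v, 2, vc)
  }
  config$velocities <- v
  config
}

kinetic_energy <- function(config) {
  if (is.null(config$velocities)) return(0)
  m <- atom_masses(config)
  0.5 * sum(m * rowSums(config$velocities^2)) / .const$acc
}

instantaneous_temperature <- function(config) {
  n <- nrow(config$positions)
  2 * kinetic_energy(config) / (3 * n * .const$kB)
}

#' MD state
#'
#' A configuration with time, the cached energy breakdown and forces, kinetic
#' energy, and instantaneous temperature `T = 2 KE / (3 N k_B)` (no
#' constraints; the model is fully flexible).
#'
#' @param config a [configuration()] with velocities (or zero velocities).
#' @param backend an [energy_backend()].
#' @param time time, fs.
#' @return list of class `aq_md_state`.
#' @export
md_state <- function(config, backend, time = 0) {
  if (is.null(config$velocities))
    config$velocities <- matrix(0, nrow(config$positions), 3)
  ev <- backend(config)
  structure(list(config = config, time = time, eval = ev,
                 KE = kinetic_energy(config),
                 T_inst = instantaneous_temperature(config)),
            class = "aq_md_state")
}

#' One velocity-Verlet step
#'
#' Standard symplectic update using the cached forces; time advances by `dt`.
#'
#' @param state an [md_state()].
#' @param dt time step, fs.
#' @param backend an [energy_backend()].
#' @return the advanced `aq_md_state`.
#' @export
velocity_verlet_step <- function(state, dt, backend) {
  cfg <- state$config
  m <- atom_masses(cfg)
  a <- state$eval$forces / m * .const$acc   # A/fs^2
  v <- cfg$velocities + 0.5 * dt * a
  cfg$positions <- cfg$positions + dt * v
  ev <- backend(cfg)
  a2 <- ev$forces / m * .const$acc
  cfg$velocities <- v + 0.5 * dt * a2
  structure(list(config = cfg, time = state$time + dt, eval = ev,
                 KE = kinetic_energy(cfg),
                 T_inst = instantaneous_temperature(cfg)),
            class = "aq_md_state")
}

#' Run molecular dynamics
#'
#' NVE velocity Verlet or NVT via the BAOAB Langevin splitting (friction
#' default 1/ps), with an explicit seed for every stochastic path.  Frames
#' and an energy log are recorded at `stride`.  A numerical blow-up (any
#' force beyond `force_limit`) aborts with diagnostics.
#'
#' @param config starting [configuration()]; velocities are drawn from the
#'   Maxwell-Boltzmann distribution at `T_K` when absent.
#' @param backend an [energy_backend()].
#' @param ensemble `"NVE"` or `"NVT"`.
#' @param T_K target temperature, K (NVT initialization and thermostat).
#' @param dt time step, fs.
#' @param steps number of steps.
#' @param stride recording stride, steps.
#' @param seed integer seed (mandatory; drives velocity draw and thermostat).
#' @param friction Langevin friction, 1/ps.
#' @param force_limit abort threshold, kcal/mol/A.
#' @return list of class `aq_trajectory`: `frames` (configurations with
#'   velocities), `charges` per frame (when the backend provides them),
#'   `energy` log data.frame, `dt`, `stride`.
#' @export
run_md <- function(config, backend, ensemble = c("NVE", "NVT"), T_K = 298.15,
                   dt = 1, steps = 1000, stride = 10, seed, friction = 1,
                   force_limit = 1e4) {
  ensemble <- match.arg(ensemble)
  if (missing(seed)) stop("run_md requires an explicit seed")
  if (is.null(config$velocities))
    config <- init_velocities(config, T_K, seed)
  set.seed(seed + 1L)
  m <- atom_masses(config)
  gam <- friction / 1000  # 1/fs
  c1 <- exp(-gam * dt)
  c2 <- sqrt((1 - c1^2) * .const$kB * T_K / m * .const$acc)
  pos <- config$positions
  vel <- config$velocities
  ev <- backend(config)
  n <- nrow(pos)
  frames <- list(); charges <- list(); log <- list()
  record <- function(k, t, cfgv, evv) {
    cfg_rec <- config
    cfg_rec$positions <- cfgv$pos
    cfg_rec$velocities <- cfgv$vel
    frames[[length(frames) + 1L]] <<- cfg_rec
    charges[[length(charges) + 1L]] <<- evv$charges
    ke <- 0.5 * sum(m * rowSums(cfgv$vel^2)) / .const$acc
    log[[length(log) + 1L]] <<- data.frame(
      step = k, time = t, U_intra = evv$U_intra, U_vdw = evv$U_vdw,
      U_coul = evv$U_coul, U_ct = if (is.null(evv$U_ct)) 0 else evv$U_ct,
      U_total = evv$U_total, KE = ke,
      T_inst = 2 * ke / (3 * n * .const$kB))
  }
  record(0L, 0, list(pos = pos, vel = vel), ev)
  for (k in seq_len(steps)) {
    a <- ev$forces / m * .const$acc
    vel <- vel + 0.5 * dt * a                       # B
    if (ensemble == "NVT") {
      pos <- pos + 0.5 * dt * vel                   # A
      vel <- c1 * vel + c2 * matrix(rnorm(3 * n), ncol = 3)  # O
      pos <- pos + 0.5 * dt * vel                   # A
    } else {
      pos <- pos + dt * vel
    }
    cfg <- config
    cfg$positions <- pos
    ev <- backend(cfg)
    if (max(abs(ev$forces)) > force_limit)
      stop("MD blow-up at step ", k, ": max|force| = ",
           signif(max(abs(ev$forces)), 4), " kcal/mol/A (U_total = ",
           signif(ev$U_total, 6), ")")
    vel <- vel + 0.5 * dt * (ev$forces / m * .const$acc)  # B
    if (k %% stride == 0) record(k, k * dt, list(pos = pos, vel = vel), ev)
  }
  structure(list(frames = frames, charges = charges,
                 energy = do.call(rbind, log), dt = dt, stride = stride,
                 ensemble = ensemble),
            class = "aq_trajectory")
}

#' Quasi-Newton energy minimization
#'
#' BFGS descent on the backend energy with analytic gradients, restarted
#' until the maximum force component falls below `tol` or the iteration cap
#' is reached.
#'
#' @param config starting [configuration()].
#' @param backend an [energy_backend()].
#' @param tol maximum-force threshold, kcal/mol/A.
#' @param max_rounds BFGS restarts.
#' @param maxit iterations per round.
#' @return list with the optimized `config`, `energy`, `max_force`,
#'   `converged`.
#' @export
minimize <- function(config, backend, tol = 1e-6, max_rounds = 40,
                     maxit = 500) {
  x0 <- as.numeric(t(config$positions))
  cfg <- config
  fn <- function(x) {
    cfg$positions <- matrix(x, ncol = 3, byrow = TRUE)
    backend(cfg)$U_total
  }
  gr <- function(x) {
    cfg$positions <- matrix(x, ncol = 3, byrow = TRUE)
    -as.numeric(t(backend(cfg)$forces))
  }
  x <- x0
  maxf <- Inf
  for (round in seq_len(max_rounds)) {
    res <- optim(x, fn, gr, method = "BFGS",
                 control = list(maxit = maxit, reltol = 1e-16))
    x <- res$par
    maxf <- max(abs(gr(x)))
    if (maxf < tol) break
    if (round >= 2 && maxf < 1e-2) break  # close enough for Newton polish
  }
  # Newton polish: quadratic convergence from the BFGS basin (Hessian by
  # central differences of the analytic gradient)
  if (maxf >= tol && maxf < 1e-2) {
    n <- length(x)
    for (it in seq_len(25)) {
      g <- gr(x)
      maxf <- max(abs(g))
      if (maxf < tol) break
      h <- 1e-4
      H <- matrix(0, n, n)
      for (k in seq_len(n)) {
        xp <- x; xp[k] <- xp[k] + h
        xm <- x; xm[k] <- xm[k] - h
        H[, k] <- (gr(xp) - gr(xm)) / (2 * h)
      }
      H <- (H + t(H)) / 2
      step <- tryCatch(solve(H + 1e-8 * diag(n), -g),
                       error = function(e) -g)
      if (max(abs(step)) > 0.2) step <- step * 0.2 / max(abs(step))
      xn <- x + step
      if (fn(xn) <= fn(x) + 1e-12) x <- xn else x <- x - 1e-3 * g
    }
    maxf <- max(abs(gr(x)))
  }
  cfg$positions <- matrix(x, ncol = 3, byrow = TRUE)
  list(config = cfg, energy = fn(x), max_force = maxf,
       converged = maxf < tol, rounds = round)
}

#' Write a trajectory as multi-frame extended XYZ with charges
#'
#' @param traj an `aq_trajectory` from [run_md()].
#' @param path output path.
#' @export
write_trajectory <- function(traj, path) {
  write_xyz(traj$frames, path,
            charges = if (length(traj$charges) &&
                          !is.null(traj$charges[[1]])) traj$charges else NULL)
}

#' Write the trajectory energy log as TSV
#'
#' @param traj an `aq_trajectory`.
#' @param path output path.
#' @export
write_energy_log <- function(traj, path) {
  df <- traj$energy
  # header names units: kcal/mol, fs, K
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
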