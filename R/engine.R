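#' Simulation configuration
#'
#' Bundles everything one population simulation needs: the ligand field, the
#' cascade parameter set (optionally heterogeneous via a vector of `beta`
#' multiples), motor and kinematic specs, the timestep, step count, seed and
#' recording stride. The defaults follow the reference experiment scale:
#' 50,000 steps of 0.0144 s (about 12 minutes of real time) in the
#' `[-2, 2]^2` mm domain.
#'
#' @param field A field spec (see [exponential_field()]).
#' @param n_cells Number of cells.
#' @param n_steps Number of timesteps (>= 1).
#' @param dt Timestep in seconds.
#' @param params Base [cascade_params()] set (its totals are taken as the
#'   `beta = 1` reference).
#' @param beta Numeric vector of total-protein multiples; recycled across
#'   cells, so a vector of eight values over 160 cells yields eight equal
#'   subpopulations.
#' @param motor A [motor_spec()]; its `yp_star` is filled per cell from the
#'   cascade steady state at the field's background concentrations.
#' @param kinematics A [kinematic_spec()].
#' @param seed Master seed (non-negative integer). Spawns one independent
#'   random stream per cell; all stochasticity derives from it.
#' @param record_stride Record every this-many steps (plus the initial and
#'   final states).
#' @param init `"local"`: each cell starts with its cascade adapted to the
#'   ligand concentrations at its initial position (default);
#'   `"background"`: all cells start adapted to the background
#'   concentrations.
#' @return An object of class `rt_simulation_config`.
#' @export
simulation_config <- function(field, n_cells = 100, n_steps = 50000,
                              dt = 0.0144, params = default_cascade_params(),
                              beta = 1, motor = motor_spec(),
                              kinematics = kinematic_spec(), seed = 1,
                              record_stride = 50,
                              init = c("local", "background")) {
  init <- match.arg(init)
  stopifnot(inherits(field, "rt_field"), inherits(params, "rt_cascade_params"),
            inherits(motor, "rt_motor_spec"),
            inherits(kinematics, "rt_kinematic_spec"),
            n_cells >= 1, n_steps >= 1, dt > 0, record_stride >= 1,
            all(beta > 0), seed >= 0)
  structure(list(field = field, n_cells = as.integer(n_cells),
                 n_steps = as.integer(n_steps), dt = dt, params = params,
                 beta = as.numeric(beta), motor = motor,
                 kinematics = kinematics, seed = as.numeric(seed),
                 record_stride = as.integer(record_stride), init = init),
            class = "rt_simulation_config")
}

# internal: number of fixed RK4 substeps per ABM timestep, from a bound on
# the fastest linearised rate of the beta-scaled cascade (stability/accuracy
# target h * lambda <= 0.5)
n_substeps <- function(params, dt) {
  to <- params$totals; ra <- params$rates
  lambda <- max(ra[["k_A"]] + ra[["k_y"]] * to[["Y"]] + ra[["k_b"]] * to[["B"]],
                ra[["k_y"]] * to[["A"]] + ra[["k_z"]] * to[["Z"]] + ra[["g_Y"]],
                ra[["k_b"]] * to[["A"]] + ra[["g_B"]],
                ra[["k_B"]] * to[["B"]])
  max(1L, as.integer(ceiling(dt * lambda / 0.5)))
}

# internal: steps at which state is recorded
recorded_steps <- function(n_steps, stride) {
  unique(c(0L, seq.int(stride, n_steps, by = stride), n_steps))
}

#' Initialise a population of cells
#'
#' Positions are uniform over the domain and headings uniform on
#' `[0, 2*pi)`, drawn from each cell's own random stream (draws 1-3 of the
#' stream; the engine consumes the same streams from draw 4 onward). Each
#' cell's reference CheY-P level `yp_star` is the cascade steady state at
#' the field's background concentrations for that cell's `beta`; the cascade
#' state starts adapted either to the local concentrations at the cell's
#' position (default) or to the background, per the config's `init`.
#'
#' @param config An [simulation_config()].
#' @return A data frame with one row per cell: `cell`, `beta`, `x`, `y`,
#'   `theta`, `m`, `Ap`, `Bp`, `Yp`, `yp_star`, `speed` (domain units/s) and
#'   `n_sub` (cascade substeps used by the engine).
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "rt_simulation_config"))
  n <- config$n_cells
  kin <- config$kinematics
  d <- kin$domain
  beta_cell <- rep_len(config$beta, n)
  u <- t(vapply(seq_len(n) - 1,
                function(s) rng_uniforms(config$seed, s, 3L),
                numeric(3)))
  x <- d[1] + u[, 1] * (d[2] - d[1])
  y <- d[3] + u[, 2] * (d[4] - d[3])
  theta <- u[, 3] * 2 * pi

  bg <- background_concentrations(config$field)
  by_beta <- lapply(unique(beta_cell), function(b) {
    pb <- scale_protein_totals(config$params, b)
    ss <- tryCatch(steady_state(pb, bg),
                   error = function(e)
                     stop("steady-state initialisation failed for beta = ", b,
                          ": ", conditionMessage(e), call. = FALSE))
    list(params = pb, ss = ss, n_sub = n_substeps(pb, config$dt))
  })
  names(by_beta) <- as.character(unique(beta_cell))

  st <- matrix(0, n, 4, dimnames = list(NULL, c("m", "Ap", "Bp", "Yp")))
  yp_star <- numeric(n)
  n_sub <- integer(n)
  for (i in seq_len(n)) {
    bb <- by_beta[[as.character(beta_cell[i])]]
    yp_star[i] <- bb$ss[["Yp"]]
    n_sub[i] <- bb$n_sub
    s0 <- if (config$init == "local")
      shift_adapted_state(bb$ss, bb$params, eval_field_at(config$field, c(x[i], y[i])))
    else bb$ss
    st[i, ] <- s0[c("m", "Ap", "Bp", "Yp")]
  }

  speed <- rep(kin$speed_domain, n)
  if (kin$speed_sd > 0) {
    for (i in seq_len(n)) {
      us <- rng_uniforms(config$seed, 1048576 + (i - 1), 2L)
      z <- sqrt(-2 * log(1 - us[1])) * cos(2 * pi * us[2])
      speed[i] <- max(kin$speed_domain +
                        kin$speed_sd * 1e-3 / kin$domain_unit_mm * z,
                      0.1 * kin$speed_domain)
    }
  }

  data.frame(cell = seq_len(n), beta = beta_cell, x = x, y = y, theta = theta,
             m = st[, "m"], Ap = st[, "Ap"], Bp = st[, "Bp"], Yp = st[, "Yp"],
             yp_star = yp_star, speed = speed, n_sub = n_sub)
}

#' Advance one cell by one timestep
#'
#' Executes the five-stage loop on a single cell, in order: evaluate the
#' ligand field at the current position; integrate the cascade over `dt`
#' with those concentrations frozen; compute the clockwise bias from the
#' post-update CheY-P; draw the run/tumble decision; move (reorienting first
#' on a tumble) and apply the boundary rule. Intended for instrumentation
#' and tests; whole-population runs use [run_simulation()].
#'
#' @param cell A one-row data frame as produced by [initialize_population()].
#' @param config An [simulation_config()].
#' @param u Optional numeric length-3 of uniform draws (decision, sign,
#'   angle); defaults to fresh draws from the session RNG.
#' @return The updated one-row cell data frame, with the step's `bias` and
#'   `state` (`"run"`/`"tumble"`) attached as columns.
#' @export
step_cell <- function(cell, config, u = stats::runif(3)) {
  stopifnot(inherits(config, "rt_simulation_config"), nrow(cell) == 1L)
  pb <- scale_protein_totals(config$params, cell$beta)
  conc <- eval_field_at(config$field, c(cell$x, cell$y))
  lt <- ligand_terms(pb$receptor, conc)
  st <- cascade_state(cell$m, cell$Ap, cell$Bp, cell$Yp)
  st <- rk4_substeps(st, pb, lt, config$dt,
                     if (!is.null(cell$n_sub)) cell$n_sub
                     else n_substeps(pb, config$dt))
  bias <- if (st[["Yp"]] > 0)
    1 / (1 + config$motor$prefactor *
           (cell$yp_star / st[["Yp"]])^config$motor$hill_exponent) else 0
  tumble <- bias > u[1]
  kin <- config$kinematics
  theta <- cell$theta
  if (tumble) theta <- tumble_reorient(theta, kin, u[2:3])
  sp <- if (!is.null(cell$speed)) cell$speed else kin$speed_domain
  pos <- c(cell$x + sp * sin(theta) * config$dt,
           cell$y + sp * cos(theta) * config$dt)
  pos <- apply_boundary(pos, kin)
  cell$x <- pos[1]; cell$y <- pos[2]; cell$theta <- theta
  cell$m <- st[["m"]]; cell$Ap <- st[["Ap"]]
  cell$Bp <- st[["Bp"]]; cell$Yp <- st[["Yp"]]
  cell$bias <- bias
  cell$state <- if (tumble) "tumble" else "run"
  cell
}

# internal: fixed-substep RK4 matching the compiled engine arithmetic
rk4_substeps <- function(state, params, lig_term, dt, n_sub) {
  h <- dt / n_sub
  y <- state
  for (s in seq_len(n_sub)) {
    k1 <- cascade_derivatives_fast(y, params, lig_term)
    k2 <- cascade_derivatives_fast(y + 0.5 * h * k1, params, lig_term)
    k3 <- cascade_derivatives_fast(y + 0.5 * h * k2, params, lig_term)
    k4 <- cascade_derivatives_fast(y + h * k3, params, lig_term)
    y <- clamp_state(y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), params)
  }
  y
}

#' Run a population simulation
#'
#' Advances every cell through `n_steps` five-stage timesteps. The default
#' engine is compiled; `engine = "r"` runs a pure-R reference implementation
#' that consumes the identical per-cell random streams and reproduces the
#' compiled engine's trajectories (used as a cross-check in the test suite).
#' Identical configs and seeds give identical trajectory tables.
#'
#' @param config An [simulation_config()].
#' @param engine `"cpp"` (default) or `"r"`.
#' @return An object of class `rt_simulation`: a list with `trajectories`
#'   (data frame: `step`, `time`, `cell`, `beta`, `x`, `y`, `theta`, `Yp`,
#'   `m`, `bias`, `state`), `initial` and `final` cell tables, and the
#'   `config`.
#' @examples
#' cfg <- simulation_config(exponential_field(d = 1), n_cells = 5,
#'                          n_steps = 200, record_stride = 50, seed = 42)
#' sim <- run_simulation(cfg)
#' head(sim$trajectories)
#' @export
run_simulation <- function(config, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "rt_simulation_config"))
  pop <- initialize_population(config)
  rec_steps <- recorded_steps(config$n_steps, config$record_stride)
  kin <- config$kinematics
  if (engine == "cpp") {
    out <- rt_simulate_cpp(
      n_cells = config$n_cells, n_steps = config$n_steps, dt = config$dt,
      rec_steps = as.integer(rec_steps),
      x0 = pop$x, y0 = pop$y, theta0 = pop$theta,
      state0 = as.matrix(pop[, c("m", "Ap", "Bp", "Yp")]),
      beta = pop$beta, ypstar = pop$yp_star, n_sub = pop$n_sub,
      totals0 = unname(config$params$totals), rates = unname(config$params$rates),
      receptor = receptor_encoding(config$params$receptor),
      field = encode_field(config$field),
      prefactor = config$motor$prefactor, hill = config$motor$hill_exponent,
      speed = pop$speed,
      turn_min_rad = kin$turn_range[1] * pi / 180,
      turn_max_rad = kin$turn_range[2] * pi / 180,
      boundary = if (kin$boundary == "solid") 0L else 1L,
      domain = kin$domain, seed = config$seed)
    rec <- out$records
    fin <- out$final
  } else {
    out <- simulate_engine_r(config, pop, rec_steps)
    rec <- out$records
    fin <- out$final
  }
  traj <- data.frame(
    step = as.integer(rec[, 1]), time = rec[, 1] * config$dt,
    cell = as.integer(rec[, 2]), beta = pop$beta[as.integer(rec[, 2])],
    x = rec[, 3], y = rec[, 4], theta = rec[, 5],
    Yp = rec[, 6], m = rec[, 7], bias = rec[, 8],
    state = c("run", "tumble")[rec[, 9] + 1])
  final <- data.frame(cell = pop$cell, beta = pop$beta,
                      x = fin[, 1], y = fin[, 2], theta = fin[, 3],
                      m = fin[, 4], Ap = fin[, 5], Bp = fin[, 6],
                      Yp = fin[, 7], yp_star = pop$yp_star)
  structure(list(trajectories = traj, initial = pop, final = final,
                 config = config),
            class = "rt_simulation")
}

# internal: receptor constants in engine order
receptor_encoding <- function(rc) {
  c(rc$n_cluster, rc$tar_fraction, rc$tsr_fraction,
    rc$K_tar[["off"]], rc$K_tar[["on"]], rc$K_tsr[["off"]], rc$K_tsr[["on"]],
    rc$m_offset, rc$m_slope, rc$m_range[1], rc$m_range[2])
}

# internal: pure-R reference engine; mirrors the compiled loop draw for draw
simulate_engine_r <- function(config, pop, rec_steps) {
  n <- config$n_cells
  kin <- config$kinematics
  dm <- kin$domain
  mot <- config$motor
  par_cell <- lapply(pop$beta, function(b) scale_protein_totals(config$params, b))
  draws <- lapply(seq_len(n) - 1,
                  function(s) rng_uniforms(config$seed, s, 3L + 3L * config$n_steps))
  cursor <- rep(4L, n)
  x <- pop$x; y <- pop$y; th <- pop$theta
  st <- as.matrix(pop[, c("m", "Ap", "Bp", "Yp")])
  n_rec <- length(rec_steps)
  rec <- matrix(NA_real_, n_rec * n, 9)
  rec_row <- 1L
  rec_i <- 1L
  record <- function(step, c, bias, tum) {
    rec[rec_row, ] <<- c(step, c, x[c], y[c], th[c], st[c, "Yp"], st[c, "m"],
                         bias, tum)
    rec_row <<- rec_row + 1L
  }
  bias_of <- function(Yp, ys) {
    if (Yp > 0) 1 / (1 + mot$prefactor * (ys / Yp)^mot$hill_exponent) else 0
  }
  if (rec_steps[1] == 0L) {
    for (c in seq_len(n)) record(0L, c, bias_of(st[c, "Yp"], pop$yp_star[c]), NA)
    rec_i <- 2L
  }
  for (step in seq_len(config$n_steps)) {
    do_rec <- rec_i <= n_rec && rec_steps[rec_i] == step
    for (c in seq_len(n)) {
      conc <- eval_field_at(config$field, c(x[c], y[c]))
      lt <- ligand_terms(par_cell[[c]]$receptor, conc)
      st[c, ] <- rk4_substeps(st[c, ], par_cell[[c]], lt, config$dt, pop$n_sub[c])
      bias <- bias_of(st[c, "Yp"], pop$yp_star[c])
      u <- draws[[c]][cursor[c]]
      cursor[c] <- cursor[c] + 1L
      tumble <- bias > u
      if (tumble) {
        uu <- draws[[c]][cursor[c] + 0:1]
        cursor[c] <- cursor[c] + 2L
        th[c] <- tumble_reorient(th[c], kin, uu)
      }
      x[c] <- x[c] + pop$speed[c] * sin(th[c]) * config$dt
      y[c] <- y[c] + pop$speed[c] * cos(th[c]) * config$dt
      pos <- apply_boundary(c(x[c], y[c]), kin)
      x[c] <- pos[1]; y[c] <- pos[2]
      if (do_rec) record(step, c, bias, as.numeric(tumble))
    }
    if (do_rec) rec_i <- rec_i + 1L
  }
  fin <- cbind(x, y, th, st[, "m"], st[, "Ap"], st[, "Bp"], st[, "Yp"])
  list(records = rec, final = fin)
}

#' @export
print.rt_simulation <- function(x, ...) {
  cfg <- x$config
  cat("<simulation>", cfg$n_cells, "cells,", cfg$n_steps, "steps of",
      cfg$dt, "s (", round(cfg$n_steps * cfg$dt / 60, 1), "min ), seed",
      cfg$seed, "\n")
  cat("  beta values:", paste(unique(x$initial$beta), collapse = ", "), "\n")
  cat("  trajectories:", nrow(x$trajectories), "records\n")
  invisible(x)
}

#' Total-protein-concentration sweep across gradient steepnesses
#'
#' Runs one mixed-`beta` population per gradient steepness `d` and
#' summarises, per `(d, beta)` subpopulation, the final mean distance to the
#' ligand peak. This is the experiment probing how cell-to-cell variation in
#' total signalling-protein content changes accumulation: fast-adapting
#' (large `beta`) populations localise well in steep gradients while the
#' spread across `beta` shrinks as the gradient flattens.
#'
#' @param config An [simulation_config()] whose field is a single-species
#'   [exponential_field()]; its `d` is replaced by each sweep value, and its
#'   `beta` vector defines the subpopulations.
#' @param d Steepness divisors to sweep.
#' @return An object of class `rt_beta_sweep`: list with `summary` (data
#'   frame `d`, `beta`, `final_mean_distance`, `equilibrated`),
#'   `timecourses` (per-step mean distance by `d` and `beta`) and `sims`
#'   (the `rt_simulation` objects, named by `d`).
#' @export
run_beta_sweep <- function(config, d = c(10, 1, 0.1)) {
  stopifnot(inherits(config, "rt_simulation_config"),
            inherits(config$field, "rt_exponential_field"))
  sims <- lapply(d, function(dv) {
    f <- config$field
    f$d <- dv
    cfg <- config
    cfg$field <- f
    run_simulation(cfg)
  })
  names(sims) <- as.character(d)
  peak <- field_peak(config$field)$position
  tc <- do.call(rbind, lapply(seq_along(d), function(i) {
    m <- mean_distance_timecourse(sims[[i]], peak)
    m$d <- d[i]
    m
  }))
  summ <- do.call(rbind, lapply(seq_along(d), function(i) {
    s <- sims[[i]]
    dist <- sqrt((s$final$x - peak[1])^2 + (s$final$y - peak[2])^2)
    agg <- stats::aggregate(dist, list(beta = s$final$beta), mean)
    data.frame(d = d[i], beta = agg$beta, final_mean_distance = agg$x,
               equilibrated = equilibrium_reached(sims[[i]], peak))
  }))
  structure(list(summary = summ, timecourses = tc, sims = sims),
            class = "rt_beta_sweep")
}

# internal diagnostic: population mean distance-to-peak changes < 2% over the
# final 10% of recorded steps (reported, never enforced)
equilibrium_reached <- function(sim, peak, tol = 0.02) {
  tc <- mean_distance_timecourse(sim, peak, by = NULL)
  tail_from <- stats::quantile(tc$step, 0.9, names = FALSE)
  tail <- tc$mean_distance[tc$step >= tail_from]
  if (length(tail) < 2 || mean(tail) == 0) return(TRUE)
  (max(tail) - min(tail)) / mean(tail) < tol
}

#' Two-attractant competition grid
#'
#' For every pair of MeAsp scaling `omega` and serine scaling `upsilon`,
#' runs a population in the two-peak arena of [meAsp_serine_field()] (MeAsp
#' peak at `(-1, 0)`, serine peak at `(1, 0)`) and classifies each cell's
#' final position: `x` below the threshold counts as attracted to MeAsp,
#' above it to serine. Also reports, per peak, the ratio of final to initial
#' mean distance (smaller means stronger accumulation).
#'
#' @param config An [simulation_config()]; its field is replaced by the
#'   grid's two-ligand fields (other settings, including `n_cells` and
#'   `seed`, are kept).
#' @param omega MeAsp scalings.
#' @param upsilon Serine scalings. An empty vector returns an empty result.
#' @param threshold Attraction threshold on final `x` (default 0, the
#'   midpoint between the peaks).
#' @param la0,ls0 Minimum concentrations of the two fields (mM).
#' @param keep_sims Keep the full `rt_simulation` objects (memory-heavy for
#'   large grids).
#' @return An object of class `rt_two_ligand_grid`: list with `summary`
#'   (data frame: `omega`, `upsilon`, `n_meAsp`, `n_serine`, `n_boundary`,
#'   `frac_serine`, `ratio_meAsp`, `ratio_serine`) and `sims` (named
#'   `"omega=..,upsilon=.."` if kept).
#' @export
run_two_ligand_grid <- function(config, omega = c(1, 5, 10),
                                upsilon = c(1e-6, 1e-5, 1e-4, 5e-4, 1e-3,
                                            2.5e-3, 5e-3, 7.5e-3, 1e-2, 1e-1),
                                threshold = 0, la0 = 0.1, ls0 = 0.1,
                                keep_sims = FALSE) {
  stopifnot(inherits(config, "rt_simulation_config"))
  grid <- expand.grid(upsilon = upsilon, omega = omega)
  if (nrow(grid) == 0L)
    return(structure(list(summary = data.frame(), sims = list()),
                     class = "rt_two_ligand_grid"))
  sims <- list()
  rows <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    om <- grid$omega[k]; up <- grid$upsilon[k]
    cfg <- config
    cfg$field <- meAsp_serine_field(omega = om, upsilon = up,
                                    la0 = la0, ls0 = ls0)
    sim <- run_simulation(cfg)
    counts <- attraction_counts(sim$final, threshold = threshold)
    pks <- field_peak(cfg$field)
    rows[[k]] <- data.frame(
      omega = om, upsilon = up,
      n_meAsp = counts$meAsp, n_serine = counts$serine,
      n_boundary = counts$boundary,
      frac_serine = counts$serine / nrow(sim$final),
      ratio_meAsp = accumulation_ratio(sim$initial, sim$final,
                                       pks$meAsp$position),
      ratio_serine = accumulation_ratio(sim$initial, sim$final,
                                        pks$serine$position))
    if (keep_sims)
      sims[[sprintf("omega=%g,upsilon=%g", om, up)]] <- sim
  }
  structure(list(summary = do.call(rbind, rows), sims = sims),
            class = "rt_two_ligand_grid")
}
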