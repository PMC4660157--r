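test_that("population initialisation is in-domain, seeded and beta-allocated", {
  cfg <- quick_config(n_cells = 24, beta = beta_ladder, seed = 5)
  pop <- initialize_population(cfg)
  expect_equal(nrow(pop), 24)
  expect_true(all(pop$x >= -2 & pop$x <= 2 & pop$y >= -2 & pop$y <= 2))
  expect_true(all(pop$theta >= 0 & pop$theta < 2 * pi))
  expect_equal(as.vector(table(pop$beta)), rep(3L, 8))
  expect_identical(pop, initialize_population(cfg))
  # different seed, different population
  cfg2 <- quick_config(n_cells = 24, beta = beta_ladder, seed = 6)
  expect_false(any(initialize_population(cfg2)$x == pop$x))
  # reference CheY-P level equals the per-beta background steady state
  ss1 <- steady_state(cfg$params, background_concentrations(cfg$field))
  expect_equal(unique(pop$yp_star[pop$beta == 1]), ss1[["Yp"]])
})

test_that("cells start adapted: a uniform field holds the cascade at steady state", {
  cfg <- simulation_config(constant_field(0.1, species = "meAsp"),
                           n_cells = 6, n_steps = 300, record_stride = 50,
                           seed = 2)
  sim <- run_simulation(cfg)
  tr <- sim$trajectories
  expect_equal(tr$Yp, rep(steady_state(cfg$params, c(meAsp = 0.1))[["Yp"]],
                          nrow(tr)), tolerance = 1e-6)
  # tumble frequency stays at the unstimulated bias (~0.213): binomial band
  dec <- tr$state[tr$step > 0]
  b0 <- 1 / 4.7
  expect_lt(abs(mean(dec == "tumble") - b0),
            3 * sqrt(b0 * (1 - b0) / length(dec)))
})

test_that("forced bias extremes give straight swimming or perpetual reorientation", {
  cfg <- quick_config(n_cells = 1, n_steps = 30, seed = 9)
  pop <- initialize_population(cfg)
  # an enormous reference level makes the bias ~0: pure straight run
  run_only <- pop
  run_only$yp_star <- 1e6
  cell <- run_only
  for (i in 1:30) {
    prev <- cell
    cell <- step_cell(cell, cfg, u = c(runif(1), 0.5, 0.5))
    expect_equal(cell$state, "run")
    expect_equal(cell$theta, prev$theta)
  }
  # a tiny reference level makes the bias ~1: a tumble every step
  tum_only <- pop
  tum_only$yp_star <- 1e-6
  cell <- tum_only
  n_turn <- 0
  for (i in 1:30) {
    prev <- cell
    cell <- step_cell(cell, cfg, u = c(runif(1), runif(1), runif(1)))
    expect_equal(cell$state, "tumble")
    n_turn <- n_turn + (cell$theta != prev$theta)
  }
  expect_equal(n_turn, 30)
})

test_that("compiled and pure-R engines produce identical trajectories", {
  cfg <- quick_config(n_cells = 5, n_steps = 80, beta = c(1, 4), seed = 13)
  a <- run_simulation(cfg, engine = "cpp")
  b <- run_simulation(cfg, engine = "r")
  num <- c("x", "y", "theta", "Yp", "m", "bias")
  expect_equal(as.matrix(a$trajectories[num]), as.matrix(b$trajectories[num]),
               tolerance = 1e-12)
  expect_identical(a$trajectories$state, b$trajectories$state)
  expect_equal(a$final, b$final, tolerance = 1e-12)
})

test_that("simulations are reproducible and cells never leave the domain", {
  cfg <- quick_config(n_cells = 8, n_steps = 400, seed = 21,
                      field = exponential_field(d = 0.1))
  s1 <- run_simulation(cfg)
  s2 <- run_simulation(cfg)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_true(all(abs(s1$trajectories$x) <= 2 & abs(s1$trajectories$y) <= 2))
  # periodic boundary also keeps every record inside
  cfgp <- quick_config(n_cells = 8, n_steps = 400, seed = 21,
                       kinematics = kinematic_spec(boundary = "periodic"))
  sp <- run_simulation(cfgp)
  expect_true(all(sp$trajectories$x >= -2 & sp$trajectories$x < 2 + 1e-12))
})

test_that("in a uniform field the population shows no systematic drift", {
  cfg <- simulation_config(constant_field(0.1, species = "meAsp"),
                           n_cells = 60, n_steps = 2000, record_stride = 500,
                           seed = 4)
  sim <- run_simulation(cfg)
  disp_x <- sim$final$x - sim$initial$x
  disp_y <- sim$final$y - sim$initial$y
  # 3-sigma band from the empirical per-cell displacement spread
  expect_lt(abs(mean(disp_x)), 3 * sd(disp_x) / sqrt(length(disp_x)))
  expect_lt(abs(mean(disp_y)), 3 * sd(disp_y) / sqrt(length(disp_y)))
})

test_that("the beta sweep reduces to independent simulations and summarises them", {
  cfg <- quick_config(n_cells = 8, n_steps = 120, beta = c(1, 4), seed = 31,
                      field = exponential_field(d = 1))
  sw <- run_beta_sweep(cfg, d = c(1, 0.1))
  expect_equal(sort(unique(sw$summary$d)), c(0.1, 1))
  expect_equal(sort(unique(sw$summary$beta)), c(1, 4))
  # the d = 1 member equals a plain run with the same config
  direct <- run_simulation(cfg)
  expect_identical(sw$sims[["1"]]$trajectories, direct$trajectories)
  dist <- sqrt(direct$final$x^2 + direct$final$y^2)
  expect_equal(sw$summary$final_mean_distance[sw$summary$d == 1],
               as.vector(tapply(dist, direct$final$beta, mean)))
})

test_that("the two-ligand grid counts attraction per scaling pair", {
  cfg <- quick_config(n_cells = 6, n_steps = 120, seed = 8)
  gr <- run_two_ligand_grid(cfg, omega = 1, upsilon = c(1e-4, 1e-1))
  expect_equal(nrow(gr$summary), 2)
  expect_equal(gr$summary$n_meAsp + gr$summary$n_serine + gr$summary$n_boundary,
               rep(6, 2))
  empty <- run_two_ligand_grid(cfg, omega = 1, upsilon = numeric(0))
  expect_equal(nrow(empty$summary), 0)
})
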