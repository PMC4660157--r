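test_that("receptor free energy matches its closed form", {
  rc <- tar_only_receptor(n_cluster = 6)
  # single species, f_m = 0: F = 6 * log((1 + 0.1/0.02)/(1 + 0.1/0.5))
  expect_equal(receptor_free_energy(rc, m = 0, c(meAsp = 0.1)),
               6 * log(6 / 1.2))
  # no ligand: only the methylation term remains
  rc2 <- receptor_spec(m_offset = 1, m_slope = 0.5)
  expect_equal(receptor_free_energy(rc2, m = 2, c(meAsp = 0, serine = 0)),
               rc2$n_cluster * (1 - 0.5 * 2))
  expect_error(receptor_free_energy(rc, 0, c(meAsp = -1)), ">= 0")
  expect_error(receptor_spec(K_tar = c(off = 0.5, on = 0.5)), "K_off < K_on")
})

test_that("receptor activity is the logistic of the free energy", {
  expect_equal(receptor_activity(0), 0.5)
  expect_equal(receptor_activity(log(3)), 0.25)
  expect_equal(receptor_activity(700), 0, tolerance = 1e-12)
  F <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(receptor_activity(F)) < 0))
})

test_that("cascade derivatives vanish at steady state and respect structure", {
  conc <- c(meAsp = 0.1)
  ss <- steady_state(default_params, conc)
  d <- cascade_derivatives(ss[c("m", "Ap", "Bp", "Yp")], default_params, conc)
  expect_lt(max(abs(d)), 1e-8)
  # phosphotransfer to CheY vanishes as Yp approaches the CheY total
  YT <- default_params$totals[["Y"]]
  st_full <- cascade_state(m = ss[["m"]], Ap = ss[["Ap"]], Bp = ss[["Bp"]],
                           Yp = YT)
  dY <- cascade_derivatives(st_full, default_params, conc)[["Yp"]]
  ra <- default_params$rates
  expect_equal(dY, -(ra[["k_z"]] * default_params$totals[["Z"]] + ra[["g_Y"]]) * YT)
})

test_that("integration preserves state bounds and fixed points", {
  conc <- c(meAsp = 0.1)
  ss <- steady_state(default_params, conc)
  st0 <- cascade_state(ss[["m"]], ss[["Ap"]], ss[["Bp"]], ss[["Yp"]])
  expect_equal(integrate_cascade(st0, default_params, conc, dt = 0), st0)
  for (dt in c(0.0144, 1, 30)) {
    expect_equal(integrate_cascade(st0, default_params, conc, dt), st0,
                 tolerance = 1e-6)
  }
  # from assorted off-equilibrium states the state never leaves its box
  to <- default_params$totals
  starts <- list(cascade_state(0, 0, 0, 0),
                 cascade_state(10, to[["A"]], to[["B"]], to[["Y"]]),
                 cascade_state(5, to[["A"]] / 3, 0, to[["Y"]]))
  for (st in starts) for (cc in c(0, 0.1, 5)) {
    out <- integrate_cascade(st, default_params, c(meAsp = cc), dt = 2)
    expect_true(out[["m"]] >= 0 && out[["m"]] <= 10)
    expect_true(out[["Ap"]] >= 0 && out[["Ap"]] <= to[["A"]])
    expect_true(out[["Bp"]] >= 0 && out[["Bp"]] <= to[["B"]])
    expect_true(out[["Yp"]] >= 0 && out[["Yp"]] <= to[["Y"]])
  }
})

test_that("adaptive integrator agrees with a fine fixed-step RK4 reference", {
  # independent route: classic RK4 at dt/100 on a smooth relaxation
  conc <- c(meAsp = 0.25)
  st <- cascade_state(m = 3, Ap = 1, Bp = 0.5, Yp = 2)
  dt <- 0.5
  lt <- runtumble:::ligand_terms(default_params$receptor, conc)
  y <- st
  h <- dt / 100
  for (i in 1:100) {
    k1 <- runtumble:::cascade_derivatives_fast(y, default_params, lt)
    k2 <- runtumble:::cascade_derivatives_fast(y + h / 2 * k1, default_params, lt)
    k3 <- runtumble:::cascade_derivatives_fast(y + h / 2 * k2, default_params, lt)
    k4 <- runtumble:::cascade_derivatives_fast(y + h * k3, default_params, lt)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out <- integrate_cascade(st, default_params, conc, dt)
  expect_equal(out, y, tolerance = 1e-6)
})

test_that("steady state solves the system and anchors the CheY-P reference", {
  ss <- steady_state(default_params, c(meAsp = 0.1))
  expect_lt(max(abs(cascade_derivatives(ss[c("m", "Ap", "Bp", "Yp")],
                                        default_params, c(meAsp = 0.1)))),
            1e-9)
  # calibration anchor of the default parameter set
  expect_equal(ss[["Yp"]], 4.043, tolerance = 1e-3)
  # deterministic
  expect_identical(unclass(ss), unclass(steady_state(default_params, c(meAsp = 0.1))))
})

test_that("perfect adaptation: steady CheY-P is ligand-independent", {
  Yp <- vapply(c(0.05, 0.1, 0.5, 2),
               function(L) steady_state(default_params, c(meAsp = L))[["Yp"]],
               numeric(1))
  expect_lt(max(Yp) - min(Yp), 1e-6)
})

test_that("scaling protein totals multiplies totals only and is invertible", {
  p2 <- scale_protein_totals(default_params, 2)
  expect_equal(p2$totals, default_params$totals * 2)
  expect_equal(p2$rates, default_params$rates)
  expect_equal(p2$beta, 2)
  back <- scale_protein_totals(p2, 1 / 2)
  expect_equal(back$totals, default_params$totals)
  expect_equal(scale_protein_totals(default_params, 1), default_params)
  expect_error(scale_protein_totals(default_params, 0), "positive")
  expect_error(scale_protein_totals(default_params, -2), "positive")
  # doubling totals lowers the steady phosphorylated fractions
  f1 <- steady_state(default_params, c(meAsp = 0.1))
  f2 <- steady_state(p2, c(meAsp = 0.1))
  expect_lt(f2[["Yp"]] / p2$totals[["Y"]],
            f1[["Yp"]] / default_params$totals[["Y"]])
  expect_lt(f2[["Ap"]] / p2$totals[["A"]],
            f1[["Ap"]] / default_params$totals[["A"]])
})

test_that("step response dips, recovers, and a null step has zero adaptation time", {
  expect_equal(adaptation_time(default_params, 0.1, 0.1), 0)
  sr <- step_response(default_params, 0.1, 0.2)
  expect_lt(sr$Yp_extremum, sr$Yp_pre)           # attractant up-step suppresses CheY-P
  expect_equal(sr$Yp_final, sr$Yp_pre, tolerance = 0.15)
  expect_gt(sr$adaptation_time, 0)
})

test_that("sensitivity matches the analytic MWC gain and vanishes off-range", {
  rc <- default_params$receptor
  for (L in c(0.05, 0.1, 0.3)) {
    S <- sensitivity(default_params, L)
    phi <- attr(steady_state(default_params, c(meAsp = L)), "activity")
    S_analytic <- (1 - phi) * rc$n_cluster * rc$tar_fraction *
      (L / (rc$K_tar[["off"]] + L) - L / (rc$K_tar[["on"]] + L))
    expect_equal(S, S_analytic, tolerance = 1e-3)
    expect_gt(S, 0)
  }
  expect_lt(sensitivity(default_params, 1e-7), 1e-3)
  expect_lt(sensitivity(default_params, 1e4), 1e-2)
  expect_error(sensitivity(default_params, -1), "positive")
})
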