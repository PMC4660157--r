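test_that("run kinematics displace at the swim speed along the heading", {
  spec <- kinematic_spec()               # 29 um/s, 0.2 mm domain units
  c_du <- spec$speed_domain
  # heading 0 is the +y axis
  expect_equal(run_step(c(0, 0), 0, spec, dt = 1), c(0, c_du))
  expect_equal(run_step(c(0, 0), pi / 2, spec, dt = 1), c(c_du, 0),
               tolerance = 1e-12)
  # displacement magnitude is exactly c * dt for any heading
  for (th in seq(0, 2 * pi, length.out = 13)) {
    p <- run_step(c(0.3, -0.8), th, spec, dt = 0.0144)
    expect_equal(sqrt(sum((p - c(0.3, -0.8))^2)), c_du * 0.0144)
  }
  # converted back to physical units the speed is the configured 29 um/s
  expect_equal(c_du * spec$domain_unit_mm * 1e3, 29)
})

test_that("tumble angles are uniform in [18, 98] degrees with random sign", {
  spec <- kinematic_spec()
  n <- 1e5
  u <- matrix(rng_uniforms(seed = 3, stream = 5, 2L * n), ncol = 2, byrow = TRUE)
  turns <- vapply(seq_len(n), function(i) {
    th <- tumble_reorient(0, spec, u[i, ])
    if (th > pi) th - 2 * pi else th  # signed turn from heading 0
  }, numeric(1))
  deg <- turns * 180 / pi
  expect_true(all(abs(deg) >= 18 - 1e-9 & abs(deg) <= 98 + 1e-9))
  expect_equal(mean(abs(deg)), 58, tolerance = 0.3 / 58)
  # sign symmetry: signed mean ~ 0 (3-sigma of the signed-angle sd)
  expect_lt(abs(mean(deg)), 3 * sd(deg) / sqrt(n))
})

test_that("a tumble reorients first and then moves the full step", {
  spec <- kinematic_spec()
  out <- tumble_step(c(0, 0), 1.2, spec, dt = 0.0144, u = c(0.3, 0.7))
  expect_equal(out$heading, tumble_reorient(1.2, spec, c(0.3, 0.7)))
  expect_equal(out$position,
               run_step(c(0, 0), out$heading, spec, dt = 0.0144))
  expect_equal(sqrt(sum(out$position^2)), spec$speed_domain * 0.0144)
  # identical draws give identical tumbles (determinism)
  out2 <- tumble_step(c(0, 0), 1.2, spec, dt = 0.0144, u = c(0.3, 0.7))
  expect_identical(out, out2)
})

test_that("boundary rules reproduce the worked examples", {
  solid <- kinematic_spec(boundary = "solid")
  expect_equal(apply_boundary(c(2.05, 1), solid), c(2, 1))
  periodic <- kinematic_spec(boundary = "periodic")
  expect_equal(apply_boundary(c(1, 2), periodic), c(1, -2))
  # interior positions pass through unchanged
  for (p in list(c(0, 0), c(-1.99, 1.99), c(0.5, -1)))
    expect_equal(apply_boundary(p, solid), p)
  expect_equal(apply_boundary(c(0.5, -1), periodic), c(0.5, -1))
})

test_that("solid clamps toward the domain and periodic wraps by its width", {
  solid <- kinematic_spec(boundary = "solid")
  periodic <- kinematic_spec(boundary = "periodic")
  pts <- list(c(2.4, -2.3), c(-5, 0.2), c(3, 3), c(1.2, -2.05))
  for (p in pts) {
    ps <- apply_boundary(p, solid)
    expect_true(all(ps >= -2 & ps <= 2))
    expect_true(all(abs(ps) <= abs(p) + 1e-12))
    pp <- apply_boundary(p, periodic)
    expect_true(all(pp >= -2 & pp < 2 + 1e-12))
    expect_equal((pp - p) %% 4, c(0, 0), tolerance = 1e-12)
  }
})
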