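test_that("exponential field evaluates to its closed form", {
  f <- exponential_field(l0 = 0.1, d = 10, center = c(0, 0), scaling = 1)
  expect_equal(unname(eval_field_at(f, c(0, 0))), 1.1)
  f1 <- exponential_field(l0 = 0.1, d = 1)
  expect_equal(unname(eval_field_at(f1, c(1, 0))), 0.1 + exp(-1))
  # far from the peak the exponential term vanishes
  expect_equal(unname(eval_field_at(f1, c(200, 0))), 0.1, tolerance = 1e-12)
  # value is always named by species
  expect_named(eval_field_at(f1, c(0, 0)), "meAsp")
})

test_that("two-ligand and constant fields return per-species concentrations", {
  tl <- meAsp_serine_field(omega = 1, upsilon = 0.0025)
  at_meAsp_peak <- eval_field_at(tl, c(-1, 0))
  expect_equal(at_meAsp_peak[["meAsp"]], 1.1)
  expect_equal(at_meAsp_peak[["serine"]], 0.0025 * (0.1 + exp(-4)))
  at_serine_peak <- eval_field_at(tl, c(1, 0))
  expect_equal(at_serine_peak[["serine"]], 0.0025 * (0.1 + 1))
  cf <- constant_field(0.1, species = "serine")
  for (pos in list(c(0, 0), c(-1.7, 1.3), c(2, -2)))
    expect_equal(unname(eval_field_at(cf, pos)), 0.1)
  expect_error(eval_field_at(structure(list(), class = "lm"), c(0, 0)),
               "unknown field")
})

test_that("field peaks equal scaling * (l0 + 1) at the center", {
  expect_equal(field_peak(exponential_field(l0 = 0.1, scaling = 5))$concentration,
               5.5)
  expect_equal(field_peak(exponential_field(l0 = 0.1, scaling = 0.0075,
                                            species = "serine"))$concentration,
               8.25e-3)
  expect_equal(field_peak(exponential_field(l0 = 0, scaling = 1))$concentration, 1)
  # peak matches direct evaluation at the center to machine precision
  f <- exponential_field(l0 = 0.3, d = 0.7, center = c(0.4, -1.1), scaling = 2.5)
  pk <- field_peak(f)
  expect_identical(pk$position, c(0.4, -1.1))
  expect_equal(unname(eval_field_at(f, pk$position)), pk$concentration)
  expect_error(field_peak(constant_field(0.1)), "no unique peak")
})

test_that("field specs validate their parameters", {
  expect_error(exponential_field(d = 0), "'d' must be > 0")
  expect_error(exponential_field(d = -1), "'d' must be > 0")
  expect_error(exponential_field(l0 = -0.1), "'l0'")
  expect_error(exponential_field(scaling = 0), "'scaling'")
  expect_error(two_ligand_field(exponential_field(species = "meAsp"),
                                exponential_field(species = "meAsp")),
               "species")
})

test_that("fields are radially symmetric, monotone in radius, flatter for larger d", {
  f <- exponential_field(l0 = 0.1, d = 1)
  for (pos in list(c(0.3, 1.2), c(-1, 0.5), c(1.9, -1.9))) {
    expect_equal(eval_field_at(f, pos), eval_field_at(f, -pos))
  }
  r <- seq(0.1, 2.5, by = 0.2)
  vals <- vapply(r, function(ri) unname(eval_field_at(f, c(ri, 0))), numeric(1))
  expect_true(all(diff(vals) < 0))
  # at fixed radius the value increases with d (flatter field)
  v_by_d <- vapply(c(0.1, 1, 10), function(d)
    unname(eval_field_at(exponential_field(l0 = 0.1, d = d), c(1, 0))),
    numeric(1))
  expect_true(all(diff(v_by_d) > 0))
})

test_that("background concentrations are the far-field levels", {
  expect_equal(background_concentrations(exponential_field(l0 = 0.1, scaling = 5)),
               c(meAsp = 0.5))
  bg <- background_concentrations(meAsp_serine_field(omega = 1, upsilon = 0.01))
  expect_equal(bg, c(meAsp = 0.1, serine = 0.001))
})
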