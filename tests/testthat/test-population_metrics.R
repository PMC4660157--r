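test_that("mean distance timecourse agrees with hand-computed fixtures", {
  traj <- make_fixture("toy_trajectories")
  # cells sit at (1,0), (0,2), (-2,-1): distances 1, 2, sqrt(5) from origin
  tc <- mean_distance_timecourse(traj, c(0, 0), by = NULL)
  expect_equal(tc$mean_distance, rep(mean(c(1, 2, sqrt(5))), 5))
  # grouped by beta: cells 1-2 are beta 1, cell 3 is beta 4
  tcb <- mean_distance_timecourse(traj, c(0, 0))
  expect_equal(tcb$mean_distance[tcb$beta == 1], rep(1.5, 5))
  expect_equal(tcb$mean_distance[tcb$beta == 4], rep(sqrt(5), 5))
  # all cells at the peak give zero everywhere
  at_peak <- transform(traj, x = 0.5, y = -0.25)
  expect_equal(mean_distance_timecourse(at_peak, c(0.5, -0.25), by = NULL)$mean_distance,
               rep(0, 5))
})

test_that("attraction counts partition the population", {
  final <- data.frame(x = c(-0.5, -0.5, 0.5, 0.5), y = 0)
  ct <- attraction_counts(final)
  expect_equal(ct, list(meAsp = 2L, serine = 2L, boundary = 0L))
  all_left <- data.frame(x = rep(-1, 7), y = 0)
  expect_equal(attraction_counts(all_left)$meAsp, 7L)
  with_tie <- data.frame(x = c(-1, 0, 1), y = 0)
  ct2 <- attraction_counts(with_tie)
  expect_equal(ct2$boundary, 1L)
  expect_equal(ct2$meAsp + ct2$serine + ct2$boundary, 3L)
  # threshold is configurable
  expect_equal(attraction_counts(final, threshold = 1)$meAsp, 4L)
})

test_that("accumulation ratio matches arithmetic and its invariances", {
  init <- data.frame(x = c(2, 0), y = c(0, 1))
  expect_equal(accumulation_ratio(init, init, c(0, 0)), 1)
  halved <- data.frame(x = c(1, 0), y = c(0, 0.5))
  expect_equal(accumulation_ratio(init, halved, c(0, 0)), 0.5)
  # two-cell fixture, hand-computed: (3,4) and (0,2) -> (1,0) and (0,-1)
  i2 <- data.frame(x = c(3, 0), y = c(4, 2))
  f2 <- data.frame(x = c(1, 0), y = c(0, -1))
  expect_equal(accumulation_ratio(i2, f2, c(0, 0)), (1 + 1) / (5 + 2))
  # invariant to relabelling cells and to rigid rotation about the peak
  expect_equal(accumulation_ratio(i2[2:1, ], f2, c(0, 0)), 2 / 7)
  rot <- function(df, a) data.frame(x = cos(a) * df$x - sin(a) * df$y,
                                    y = sin(a) * df$x + cos(a) * df$y)
  expect_equal(accumulation_ratio(rot(i2, 1.1), rot(f2, 1.1), c(0, 0)), 2 / 7)
  expect_error(accumulation_ratio(data.frame(x = 0, y = 0),
                                  data.frame(x = 1, y = 0), c(0, 0)),
               "undefined")
})

test_that("Hill fits recover generating parameters on noiseless data", {
  u <- c(1e-6, 1e-5, 1e-4, 5e-4, 1e-3, 2.5e-3, 5e-3, 7.5e-3, 1e-2, 1e-1)
  # property over the plausible (K, n) plane, 1% recovery everywhere
  for (K in c(1e-4, 1e-3, 2.71e-3, 2e-2)) for (n in c(1, 3.166, 6)) {
    f <- u^n / (K^n + u^n)
    fit <- hill_fit(u, f)
    expect_equal(fit$K, K, tolerance = 0.01)
    expect_equal(fit$n, n, tolerance = 0.01)
  }
})

test_that("Hill fit is scale-equivariant and rejects degenerate data", {
  u <- 10^seq(-6, -1, length.out = 8)
  f <- u^3 / (1e-3^3 + u^3)
  base <- hill_fit(u, f)
  shifted <- hill_fit(u * 10, f)
  expect_equal(shifted$K, base$K * 10, tolerance = 1e-4)
  expect_equal(shifted$n, base$n, tolerance = 1e-4)
  expect_error(hill_fit(u, rep(0, 8)), "degenerate")
  expect_error(hill_fit(u, rep(1, 8)), "degenerate")
  expect_error(hill_fit(u[1:3], f[1:3]), "4 distinct")
})

test_that("a symmetric two-point bracket localises K between its points", {
  # brute-force grid oracle: for data symmetric about K the best K lies between
  u <- c(1e-4, 1e-3, 4e-4 / 1.6, 1.6e-3 * 2.5)
  K_true <- sqrt(1e-4 * 1e-3) * 2
  f <- u^2 / (K_true^2 + u^2)
  grid <- 10^seq(-5, -1, length.out = 400)
  sse <- vapply(grid, function(K) sum((u^2 / (K^2 + u^2) - f)^2), numeric(1))
  K_grid <- grid[which.min(sse)]
  fit <- hill_fit(u, f)
  expect_equal(fit$K, K_grid, tolerance = 0.02)
  expect_true(fit$K > min(u) && fit$K < max(u))
})
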