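test_that("macroscopic rates follow mass action and detailed balance at b0", {
  m <- model_b4_100()
  w <- macroscopic_rates(m, 1)
  expect_equal(unlist(w), c(w_plus1 = 0.5, w_minus1 = 3, w_plus2 = 1, w_minus2 = 4))

  # at the detailed-balance point every channel balances individually
  eq <- equilibrium_point(m)
  w0 <- macroscopic_rates(m, unname(eq["x0"]), b = unname(eq["b0"]))
  expect_equal(w0$w_plus1, w0$w_minus1, tolerance = 1e-12)
  expect_equal(w0$w_plus2, w0$w_minus2, tolerance = 1e-12)
  expect_equal(unname(w0$w_plus1), 0.5)
  expect_equal(unname(w0$w_plus2), (1 / 6)^3)

  w_zero <- macroscopic_rates(m, 0)
  expect_equal(unlist(w_zero, use.names = FALSE), c(0.5, 0, 0, 0))
  expect_error(macroscopic_rates(m, -0.1), "x must be")
})

test_that("drift vanishes at the fixed points with the analytic curvature", {
  m <- model_b4_100()
  eq <- equilibrium_point(m)
  expect_equal(ode_drift(m, eq["x0"], b = eq["b0"])$drift, 0,
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_lt(abs(ode_drift(m, ROOTS_B4[1])$drift), 1e-7)
  expect_equal(ode_drift(m, ROOTS_B4[3])$phi2_ode,
               3 * ROOTS_B4[3]^2 - 8 * ROOTS_B4[3] + 3, tolerance = 1e-12)
  expect_equal(ode_drift(m, ROOTS_B4[3])$phi2_ode, 6.8, tolerance = 1e-4)
})

test_that("fixed points match the frozen cubic roots with alternating stability", {
  m <- model_b4_100()
  fp <- fixed_points(m)
  expect_equal(fp$x_star, ROOTS_B4, tolerance = 1e-7)
  expect_equal(fp$stability, c("stable", "unstable", "stable"))
  expect_true(all(fp$curvature[c(1, 3)] > 0) && fp$curvature[2] < 0)
  # the two channel fluxes agree at every fixed point
  for (i in 1:3) {
    w <- macroscopic_rates(m, fp$x_star[i])
    expect_equal(w$w_plus1 - w$w_minus1, w$w_plus2 - w$w_minus2,
                 tolerance = 1e-9)
  }
  expect_equal(fixed_points(m, b = 1 / 6)$x_star, 1 / 6, tolerance = 1e-12)
  expect_equal(nrow(fixed_points(m, b = 2)), 1)
})

test_that("the bistable window of the sweep is a contiguous interval around b = 4", {
  m <- model_b4_100()
  grid <- seq(0.05, 6, by = 0.05)
  sw <- bifurcation_sweep(m, grid)
  n_roots <- table(factor(sw$b, levels = grid))
  tri <- as.integer(n_roots) == 3
  expect_true(any(tri))
  expect_true(all(diff(which(tri)) == 1))        # contiguous
  expect_true(tri[which.min(abs(grid - 4))])     # contains b = 4
  # single-point grids agree with fixed_points
  one <- bifurcation_sweep(m, 4)
  expect_equal(one$x_star, fixed_points(m, b = 4)$x_star)
  expect_error(bifurcation_sweep(m, numeric(0)), "nonempty")
})

test_that("equilibrium point is closed form and kills the entropy production", {
  m <- model_b4_100()
  expect_equal(unname(equilibrium_point(m)), c(1 / 6, 1 / 6))
  m2 <- schloegl(b = 1, omega = 10, k_plus1 = 3, a = 1, k_minus1 = 3)
  expect_equal(unname(equilibrium_point(m2)), c(1, 1))
  eq <- equilibrium_point(m)
  expect_equal(macroscopic_ep(m, eq["x0"], b = eq["b0"])$dsi_dt, 0,
               tolerance = 1e-14)
  expect_error(equilibrium_point(schloegl(b = 1, omega = 1, k_minus1 = 0)),
               "degenerate")
})

test_that("macroscopic entropy production matches the flux-affinity oracle at b = 4", {
  m <- model_b4_100()
  expect_equal(macroscopic_ep(m, ROOTS_B4[3])$dsi_dt, DSI_B4_HIGH, tolerance = 1e-6)
  expect_equal(macroscopic_ep(m, ROOTS_B4[1])$dsi_dt, DSI_B4_LOW, tolerance = 1e-6)
  # at a fixed point the rate reduces to F * (sum of log affinities)
  w <- macroscopic_rates(m, ROOTS_B4[3])
  F <- w$w_plus1 - w$w_minus1
  expect_equal(macroscopic_ep(m, ROOTS_B4[3])$dsi_dt,
               F * (log(w$w_plus1 / w$w_minus1) + log(w$w_plus2 / w$w_minus2)),
               tolerance = 1e-9)
  # infinite affinity at the boundary is flagged, not raised
  ep0 <- macroscopic_ep(m, 0)
  expect_true(ep0$infinite && is.infinite(ep0$dsi_dt))
})

test_that("entropy production is nonnegative for random states and parameters", {
  set.seed(41)
  for (i in 1:200) {
    m <- schloegl(b = runif(1, 0.01, 8), omega = 1,
                  k_plus1 = runif(1, 0.05, 4), k_minus1 = runif(1, 0.05, 4),
                  k_plus2 = runif(1, 0.05, 4), k_minus2 = runif(1, 0.05, 4))
    expect_gte(macroscopic_ep(m, runif(1, 0.01, 5))$dsi_dt, 0)
  }
})

test_that("fixed-point entropy production vanishes only at b0 and stays nonnegative", {
  m <- model_b4_100()
  b0 <- equilibrium_point(m)["b0"]
  grid <- seq(b0, 6, length.out = 60)
  sw <- bifurcation_sweep(m, grid)
  expect_true(all(sw$dsi_dt >= -1e-12))
  at_b0 <- sw$dsi_dt[abs(sw$b - b0) < 1e-12]
  expect_lt(max(at_b0), 1e-12)
  expect_true(all(sw$dsi_dt[sw$b > b0 + 1e-9] > 0))
})

test_that("config files round-trip model parameters and sweeps write CSV", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("k_plus1_a: 0.5", "k_minus1: 3", "k_plus2: 1", "k_minus2: 1",
               "b: 4", "omega: 100"), cfg)
  m <- read_schloegl_config(cfg)
  expect_equal(m$b, 4)
  expect_equal(m$k_plus1 * m$a, 0.5)
  writeLines(c("k_plus1_a: 0.5", "bogus: 1"), cfg)
  expect_error(read_schloegl_config(cfg), "bogus")

  out <- tempfile(fileext = ".csv")
  write_sweep_csv(bifurcation_sweep(model_b4_100(), c(2, 4)), out)
  back <- utils::read.csv(out)
  expect_equal(back$x_star[back$b == 4], ROOTS_B4, tolerance = 1e-10)
})
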