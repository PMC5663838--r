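test_that("propensities carry the combinatorial factors and macroscopic limit", {
  m <- model_b4_10()
  W <- propensities(m, 5)
  # direct arithmetic: W+1 = 0.5*10, W-1 = 3*5, W+2 = 5*4*3/100, W-2 = 4*5*4/10
  expect_equal(unlist(W), c(W_plus1 = 5, W_minus1 = 15, W_plus2 = 0.6,
                            W_minus2 = 8))
  expect_equal(propensities(m, 2)$W_plus2, 0)        # (X-2) factor
  W0 <- propensities(m, 0)
  expect_true(W0$W_plus1 > 0 && W0$W_minus1 == 0 && W0$W_plus2 == 0 &&
                W0$W_minus2 == 0)                    # reflecting at 0
  expect_error(propensities(m, -1), ">= 0")
  # W/(Omega) converges to the macroscopic rates
  m2 <- schloegl(b = 4, omega = 1e5)
  X <- round(2.5 * m2$omega)
  W <- propensities(m2, X)
  w <- macroscopic_rates(m2, X / m2$omega)
  expect_equal(W$W_minus2 / m2$omega, w$w_minus2, tolerance = 1e-4)
  expect_equal(W$W_plus2 / m2$omega, w$w_plus2, tolerance = 1e-4)
})

test_that("a single linear channel gives the Poisson stationary law", {
  m <- schloegl(b = 0, omega = 20, k_plus2 = 0, k_minus2 = 0)
  p <- stationary_distribution(m)
  lam <- 20 * 0.5 / 3
  expect_lt(tv_dist(p$pmf, stats::dpois(p$X, lam)), 1e-12)
})

test_that("stationary pmf solves the master equation and is bimodal at the ODE roots", {
  for (om in c(10, 100)) {
    m <- schloegl(b = 4, omega = om)
    p <- stationary_distribution(m)
    expect_equal(sum(p$pmf), 1, tolerance = 1e-12)
    expect_lt(p$tail_mass_bound, 1e-10)
    G <- generator_matrix(m, p$x_max)
    expect_lt(max(abs(G %*% p$pmf)), 1e-10)
  }
  p100 <- stationary_distribution(model_b4_100())
  modes <- sort(maxepp:::find_pmf_peaks(p100$pmf)) - 1
  expect_length(modes, 2)
  expect_lt(abs(modes[1] / 100 - ROOTS_B4[1]), 0.05)
  expect_lt(abs(modes[2] / 100 - ROOTS_B4[3]), 0.05)
})

test_that("transient solutions conserve probability, produce entropy and mix", {
  m <- model_b4_10()
  n <- 81
  P0 <- numeric(n); P0[1] <- 1                      # delta at X = 0
  tr <- evolve_distribution(m, P0, c(0, 2^(0:7), 150))
  expect_lt(max(abs(rowSums(tr$P) - 1)), 1e-9)
  expect_true(all(tr$dSi_dt[-1] >= -1e-12))
  ps <- stationary_distribution(m, x_max = n - 1)
  expect_lt(tv_dist(tr$P[nrow(tr$P), ], ps$pmf), 1e-6)

  # from stationarity: S constant, production balances flow at all times
  tr2 <- evolve_distribution(m, ps$pmf, seq(0, 2, by = 0.5))
  expect_lt(diff(range(tr2$S)), 1e-8)
  expect_lt(max(abs(tr2$dSi_dt + tr2$dSe_dt)), 1e-7 * max(tr2$dSi_dt))
  expect_error(evolve_distribution(m, P0 * 2, c(0, 1)), "normalized")
})

test_that("entropy balance dS/dt = dSi/dt + dSe/dt holds along a relaxation", {
  m <- model_b4_10()
  P0 <- numeric(81); P0[11] <- 1
  probe <- c(0.5, 2, 8)
  h <- 1e-4
  tr <- evolve_distribution(m, P0, c(0, as.vector(rbind(probe - h, probe, probe + h))))
  for (k in seq_along(probe)) {
    i <- 1 + 3 * (k - 1) + 2
    fd <- (tr$S[i + 1] - tr$S[i - 1]) / (2 * h)
    expect_lt(abs(fd - tr$dSi_dt[i] - tr$dSe_dt[i]), 1e-6)
  }
})

test_that("entropy rates are nonnegative and antisymmetric at stationarity", {
  m <- model_b4_10()
  ps <- stationary_distribution(m)
  er <- entropy_rates(m, ps$pmf)
  expect_gt(er$dSi_dt, 0)
  expect_lt(abs(er$dSi_dt + er$dSe_dt), 1e-9 * er$dSi_dt)
  # detailed balance at b0
  m0 <- model_eq(10)
  er0 <- entropy_rates(m0, stationary_distribution(m0)$pmf)
  expect_lt(abs(er0$dSi_dt), 1e-10)
  # second law for arbitrary normalized states
  set.seed(7)
  for (i in 1:50) {
    P <- rexp(60); P <- P / sum(P)
    expect_gte(entropy_rates(m, P)$dSi_dt, 0)
  }
})

test_that("total stationary entropy production is extensive in the volume", {
  per_om <- vapply(c(25, 50, 100), function(om) {
    m <- schloegl(b = 4, omega = om)
    entropy_rates(m, stationary_distribution(m)$pmf)$dSi_dt / om
  }, numeric(1))
  expect_lt(abs(per_om[3] / per_om[2] - 1), 0.02)
  expect_lt(abs(per_om[2] / per_om[1] - 1), 0.05)
  # converging monotonically towards the macroscopic high-state rate
  expect_true(all(diff(abs(per_om - DSI_B4_HIGH)) < 0))
})

test_that("the separatrix partition is additive and lies near x = 0.9 at b = 3.65", {
  m <- schloegl(b = 3.65, omega = 100)
  p <- stationary_distribution(m)
  pt <- partition_states(p)
  expect_false(pt$unimodal)
  expect_gte(pt$separatrix_x, 0.85)
  expect_lte(pt$separatrix_x, 0.95)
  expect_equal(sum(pt$weights), 1, tolerance = 1e-12)
  expect_true(all(pt$ep_rates >= 0))
  er <- entropy_rates(m, p$pmf)
  expect_lt(abs(sum(pt$ep_rates) - er$dSi_dt), 1e-9 * er$dSi_dt)
  # monostable driving: one state carrying everything
  m1 <- schloegl(b = 1, omega = 100)
  pt1 <- partition_states(stationary_distribution(m1))
  expect_true(pt1$unimodal)
  expect_equal(unname(pt1$weights), 1)
})

test_that("the delta-peak approximation reproduces the weight/EP ordering", {
  m <- schloegl(b = 3.65, omega = 100)
  p <- stationary_distribution(m)
  pt <- partition_states(p)
  de <- state_ep_delta_approx(m, p)
  expect_equal(order(de), order(pt$ep_rates))
  expect_equal(order(de), order(pt$weights))
  # with equal peak heights the EP ratio is the macroscopic-rate ratio
  fp <- fixed_points(m)
  st <- fp$x_star[fp$stability == "stable"]
  fake <- p
  fake$pmf[] <- 0
  fake$pmf[round(100 * st) + 1] <- 0.5
  de2 <- state_ep_delta_approx(m, fake)
  ds <- vapply(st, function(x) macroscopic_ep(m, x)$dsi_dt, numeric(1))
  expect_equal(de2[1] / de2[2], ds[1] / ds[2], tolerance = 1e-12,
               ignore_attr = TRUE)
  # high state dominates at b = 4
  m4 <- model_b4_100()
  de4 <- state_ep_delta_approx(m4, stationary_distribution(m4))
  expect_gt(de4["high"], de4["low"])
  expect_error(state_ep_delta_approx(schloegl(b = 1, omega = 100),
                                     stationary_distribution(schloegl(b = 1, omega = 100))),
               "bistable")
})

test_that("weight and entropy-production crossings of the transition are close", {
  cb <- critical_b(model_b4_100())
  expect_false(is.na(cb$b_c_ep))
  expect_lt(abs(cb$b_c - cb$b_c_ep), 0.15)
  expect_error(critical_b(model_b4_100(), bracket = c(3.7, 3.9)), "no weight")
})

test_that("exact first-passage times solve the linear first-passage system", {
  m <- schloegl(b = 2, omega = 10)
  G <- as.matrix(generator_matrix(m, 60))
  tgt <- 30
  keep <- setdiff(1:61, tgt + 1)
  tau <- solve(t(G)[keep, keep], rep(-1, length(keep)))
  expect_equal(exact_mfpt(m, 5, 30, x_max = 60), tau[which(keep == 6)],
               tolerance = 1e-8)
  expect_equal(exact_mfpt(m, 40, 30, x_max = 60), tau[which(keep == 41)],
               tolerance = 1e-8)
  # pure-birth chain: unit step takes 1/rate
  mb <- schloegl(b = 0, omega = 10, k_minus1 = 0, k_plus2 = 0, k_minus2 = 0)
  expect_equal(exact_mfpt(mb, 3, 4, x_max = 50), 1 / 5)
  expect_error(exact_mfpt(m, 5, 5), "differ")
})

test_that("pmf CSV writer round-trips at full precision", {
  m <- model_b4_10()
  p <- stationary_distribution(m)
  f <- tempfile(fileext = ".csv")
  write_pmf_csv(p, f)
  back <- utils::read.csv(f)
  expect_equal(back$P, p$pmf, tolerance = 1e-15)
})
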