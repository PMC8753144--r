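org <- particle_preset("bacterial_organelle")
dust <- particle_preset("standard_dust")
rho100 <- 5.604e-7
g100 <- 9.80665 * (6371 / 6471)^2

test_that("wind force is signed stagnation-pressure drag on the disc", {
  expect_identical(wind_force(rho100, 2e-6, 50, 50), 0)
  # quadratic in the relative wind
  expect_equal(wind_force(rho100, 2e-6, 20, 0),
               4 * wind_force(rho100, 2e-6, 10, 0), tolerance = 1e-12)
  # downward relative wind gives a downward force
  expect_lt(wind_force(rho100, 2e-6, -10, 5), 0)
  # direct arithmetic: rho * pi * r^2 * w^2 at w = 50
  expect_equal(wind_force(rho100, 2e-6, 50, 0),
               rho100 * pi * (2e-6)^2 * 2500, tolerance = 1e-12)
  expect_equal(wind_force(rho100, 2e-6, 50, 0), 1.7606e-14, tolerance = 1e-4)
  # the force at w = 50 exceeds the organelle's weight, so it can ascend
  expect_gt(wind_force(rho100, org$r, 50, 0), org$m * g100)
  expect_error(wind_force(-1, 2e-6, 10, 0), "non-negative")
})

test_that("acceleration reduces to -g at zero relative wind and 0 at threshold", {
  expect_equal(particle_acceleration(org, rho100, g100, w = 12, v = 12),
               -g100, tolerance = 1e-12)
  wth <- threshold_velocity(org, rho100, g100)
  expect_equal(particle_acceleration(org, rho100, g100, w = wth, v = 0), 0,
               tolerance = 1e-10)
  # direct evaluation at w = 50, v = 0 with g = 9.51
  expect_equal(particle_acceleration(org, rho100, 9.51, w = 50, v = 0),
               (rho100 / (2000 * 40e-9)) * 2500 - 9.51, tolerance = 1e-12)
  expect_equal(particle_acceleration(org, rho100, 9.51, w = 50, v = 0), 8.00,
               tolerance = 1e-3)
})

test_that("threshold velocity follows the balance of weight and momentum flux", {
  expect_equal(threshold_velocity(org, rho100, 9.51),
               sqrt(9.51 * 2000 * 40e-9 / rho100), tolerance = 1e-12)
  expect_equal(threshold_velocity(org, rho100, 9.51), 36.9, tolerance = 0.005)
  # quadrupling the density halves the threshold
  expect_equal(threshold_velocity(org, 4 * rho100, 9.51),
               threshold_velocity(org, rho100, 9.51) / 2, tolerance = 1e-12)
  # thinner disc at fixed bulk density: threshold scales as sqrt(h)
  thin <- particle_from_density(2000, 2e-6, 10e-9)
  expect_equal(threshold_velocity(thin, rho100, 9.51),
               threshold_velocity(org, rho100, 9.51) / 2, tolerance = 1e-12)
  expect_error(threshold_velocity(org, 0, 9.51), "positive")
})

test_that("steady state is wind minus threshold, signed", {
  expect_equal(steady_state_velocity(org, rho100, g100, 50), 13,
               tolerance = 0.02)
  # identity: steady state + threshold = w, for any inputs
  for (w in c(-10, 0, 20, 50, 120)) {
    expect_equal(steady_state_velocity(org, rho100, g100, w) +
                   threshold_velocity(org, rho100, g100), w,
                 tolerance = 1e-12)
  }
  # sub-threshold wind: negative value = quasi-steady descent rate
  expect_lt(steady_state_velocity(org, rho100, g100, 10), 0)
  # acceleration vanishes at the steady state
  vss <- steady_state_velocity(org, rho100, g100, 50)
  expect_equal(particle_acceleration(org, rho100, g100, w = 50, v = vss), 0,
               tolerance = 1e-10)
})

test_that("relaxation time is 1/sqrt(lambda g) and under a second for dust", {
  tau <- relaxation_time(dust, rho100, 9.51)
  expect_equal(tau, 1 / sqrt((rho100 / (1000 * 1e-9)) * 9.51),
               tolerance = 1e-12)
  expect_equal(tau, 0.433, tolerance = 0.002)
  expect_lt(tau, 1)
  # tau -> 0 as lambda grows (denser air)
  expect_lt(relaxation_time(dust, 1e-3, 9.51), 2e-2)
})

test_that("transient solution starts at rest, rises monotonically, stays below w", {
  v <- transient_velocity(org, rho100, 9.51, w = 50,
                          t = c(0, 0.5, 1, 2, 5, 10, 30, 100))
  expect_identical(v[1], 0)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < 50))
  # approaches the steady state at late times
  vss <- steady_state_velocity(org, rho100, 9.51, 50)
  tau <- relaxation_time(org, rho100, 9.51)
  expect_equal(transient_velocity(org, rho100, 9.51, 50, 20 * tau), vss,
               tolerance = 1e-9)
  expect_lt(abs(transient_velocity(org, rho100, 9.51, 50, 5 * tau) - vss),
            1e-3 * vss)
})

test_that("transient solution errors outside its ascent domain", {
  wth <- threshold_velocity(org, rho100, 9.51)
  expect_error(transient_velocity(org, rho100, 9.51, w = wth - 1, t = 1),
               "threshold")
  expect_error(transient_velocity(org, rho100, 9.51, w = -5, t = 1),
               "threshold")
  expect_error(transient_velocity(org, rho100, 9.51, w = 50, t = -1),
               "non-negative")
})

test_that("closed-form transient agrees with an independent RK4 integration", {
  set.seed(2024)
  n_cases <- 100
  for (i in seq_len(n_cases)) {
    rho_p <- 10^runif(1, 2, 3.5)
    h <- 10^runif(1, -9, -7)
    p <- particle_from_density(rho_p, 1e-6, h)
    rho <- 10^runif(1, -8, -5)
    g <- runif(1, 9.4, 9.81)
    wth <- threshold_velocity(p, rho, g)
    w <- wth * runif(1, 1.05, 3)
    tau <- relaxation_time(p, rho, g)
    for (tf in c(0.1, 1, 10) * tau) {
      v_closed <- transient_velocity(p, rho, g, w, tf)
      v_rk4 <- rk4_velocity(rho_p, h, rho, g, w, tf, n_steps = 1500L)
      expect_equal(v_closed, v_rk4, tolerance = 1e-6)
    }
  }
})

test_that("dynamics context bundles consistent derived quantities", {
  ctx <- dynamics_context(org, rho100, g100, w = 50, v = 0)
  expect_equal(abs(ctx$lambda), rho100 / (org$rho_p * org$h),
               tolerance = 1e-12)
  expect_equal(ctx$b, ctx$lambda / ctx$g, tolerance = 1e-12)
  expect_identical(ctx$H, 1)
  expect_equal(ctx$v_steady + ctx$threshold, 50, tolerance = 1e-12)
  # descending relative wind flips the sign factor
  ctx2 <- dynamics_context(org, rho100, g100, w = -5, v = 0)
  expect_identical(ctx2$H, -1)
  expect_lt(ctx2$lambda, 0)
})
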