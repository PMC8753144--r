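atm <- standard_atmosphere()
gm <- gravity_model()
org <- particle_preset("bacterial_organelle")
vir <- particle_preset("h1n1_virus")

# recompute the steady state independently at each recorded row
steady_state_velocity_rows <- function(p, tr, gm) {
  g <- gravity_at(gm, tr$altitudes)
  tr$winds - sqrt(g * p$rho_p * p$h / tr$densities)
}

test_that("quasi-steady rows satisfy the local steady-state relation", {
  tr <- integrate_trajectory(org, wind_episode(50, 300), atm, gm,
                             z0 = 100e3, dt = 5)
  expect_s3_class(tr, "loft_trajectory")
  v_expected <- steady_state_velocity_rows(org, tr, gm)
  expect_equal(tr$velocities, v_expected, tolerance = 1e-9)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$altitudes >= min(atm$altitudes) &
                    tr$altitudes <= max(atm$altitudes)))
})

test_that("a 7 m/s mean ascent sustained 20 minutes climbs 8.4 km", {
  # constant-density column so the steady state stays fixed; pick the wind
  # that puts the steady-state ascent at exactly 7 m/s
  rho <- 5.604e-7
  catm <- const_atmosphere(rho)
  g <- gravity_at(gm, 100e3)
  w <- 7 + threshold_velocity(org, rho, g)
  tr <- integrate_trajectory(org, wind_episode(w, 1200, rho_override = rho),
                             catm, gravity_model("constant", g0 = g),
                             z0 = 100e3, dt = 1)
  expect_equal(climb(tr), 8400, tolerance = 1e-6)
})

test_that("sub-threshold wind gives monotonic quasi-steady descent", {
  tr <- integrate_trajectory(org, wind_episode(10, 600), atm, gm,
                             z0 = 100e3, dt = 10)
  expect_true(all(diff(tr$altitudes) < 0))
  expect_true(all(tr$velocities < 0))
})

test_that("virus in a constant-density 50 m/s updraft climbs ~9 km in 1 h", {
  tr <- integrate_trajectory(vir, wind_episode(50, 3600, rho_override = 9e-8),
                             atm, gm, z0 = 110e3, dt = 5, mode = "full_ode")
  expect_equal(climb(tr), 9000, tolerance = 0.1)
  expect_identical(tr$stop_reason, "forcing_exhausted")
})

test_that("quasi-steady and full-ODE agree when forcing outlasts relaxation", {
  tau <- relaxation_time(org, density_at(atm, 100e3), gravity_at(gm, 100e3))
  dur <- ceiling(200 * tau)   # episode duration >> relaxation time
  ep <- wind_episode(50, dur)
  qs <- integrate_trajectory(org, ep, atm, gm, z0 = 100e3, dt = 1)
  fo <- integrate_trajectory(org, ep, atm, gm, z0 = 100e3, dt = 1,
                             mode = "full_ode")
  zq <- qs$altitudes[length(qs$altitudes)]
  zf <- fo$altitudes[length(fo$altitudes)]
  expect_lt(abs(zq - zf) / abs(zq - 100e3), 0.01)
})

test_that("halving the step changes the final altitude by under 0.1%", {
  for (cfg in list(list(p = org, w = 50, z0 = 100e3, dur = 1200,
                        rho = NULL),
                   list(p = vir, w = 50, z0 = 110e3, dur = 3600,
                        rho = 9e-8))) {
    t1 <- integrate_trajectory(cfg$p,
                               wind_episode(cfg$w, cfg$dur,
                                            rho_override = cfg$rho),
                               atm, gm, z0 = cfg$z0, dt = 2)
    t2 <- integrate_trajectory(cfg$p,
                               wind_episode(cfg$w, cfg$dur,
                                            rho_override = cfg$rho),
                               atm, gm, z0 = cfg$z0, dt = 1)
    expect_lt(abs(climb(t2) - climb(t1)) / abs(climb(t2)), 1e-3)
  }
})

test_that("trajectories truncate with a recorded reason at the table edge", {
  dust <- particle_preset("standard_dust")
  tr <- integrate_trajectory(dust, wind_episode(250, 600), atm, gm,
                             z0 = 199e3, dt = 1)
  expect_identical(tr$stop_reason, "table_ceiling")
  expect_equal(tr$altitudes[length(tr$altitudes)], 200e3)
  expect_lt(tr$times[length(tr$times)], 600)
})

test_that("wind-series forcing drives the integrator sample by sample", {
  ws <- synthesize_wind(amplitude = 30, period = 1200, noise_sd = 0,
                        mean_offset = 10, duration = 2400, dt = 10)
  tr <- integrate_trajectory(org, ws, atm, gm, z0 = 100e3, dt = 10)
  expect_identical(tr$stop_reason, "forcing_exhausted")
  expect_equal(tr$times[length(tr$times)], 2400)
  # winds recorded on the trajectory come from the series
  expect_true(all(tr$winds %in% ws$winds))
})

test_that("ceiling altitude matches an independent scan of the profile", {
  ce <- ceiling_altitude(vir, 50, atm, gm)
  expect_identical(attr(ce, "reason"), "threshold_match")
  # independent check: 100 m scan for the highest altitude still liftable
  zs <- seq(70e3, 200e3, by = 100)
  thr <- threshold_velocity(vir, density_at(atm, zs), gravity_at(gm, zs))
  z_scan <- zs[max(which(thr <= 50))]
  expect_lt(abs(ce - z_scan), 100)
  expect_gt(ce, 105e3)
  expect_lt(ce, 125e3)
})

test_that("ceiling rises with wind speed and reports edge conditions", {
  c1 <- ceiling_altitude(vir, 40, atm, gm)
  c2 <- ceiling_altitude(vir, 80, atm, gm)
  expect_gt(c2, c1)
  # organelle threshold at 70 km is ~1.3 m/s; below it there is no ceiling
  low <- ceiling_altitude(org, 1, atm, gm)
  expect_true(is.na(low))
  expect_identical(attr(low, "reason"), "no_ceiling")
  # dust is liftable over the whole table at extreme wind
  hi <- ceiling_altitude(particle_preset("standard_dust"), 1000, atm, gm)
  expect_identical(attr(hi, "reason"), "table_ceiling")
  expect_equal(as.numeric(hi), 200e3)
})

test_that("a particle released at its ceiling hovers there", {
  ce <- as.numeric(ceiling_altitude(vir, 50, atm, gm))
  tr <- integrate_trajectory(vir, wind_episode(50, 100), atm, gm,
                             z0 = ce, dt = 1)
  expect_lt(abs(climb(tr)), 1)
})

test_that("horizontal excursion and coherence flag follow u * t", {
  hx <- horizontal_excursion(200, 1200)
  expect_equal(hx$distance_m, 240e3)
  expect_true(hx$within_correlation)
  # boundary case: exactly the 300 km correlation length still counts
  hx2 <- horizontal_excursion(250, 1200)
  expect_equal(hx2$distance_m, 300e3)
  expect_true(hx2$within_correlation)
  expect_false(horizontal_excursion(300, 1200)$within_correlation)
  expect_equal(horizontal_excursion(0, 100)$distance_m, 0)
  expect_error(horizontal_excursion(200, 0), "positive")
})

test_that("trajectory CSV writer emits the documented schema plus sidecar", {
  tr <- integrate_trajectory(org, wind_episode(50, 60), atm, gm,
                             z0 = 100e3, dt = 10)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  expect_identical(readLines(f, n = 1L), "t_s,z_m,v_m_s,w_m_s,rho_kg_m3")
  back <- read.csv(f)
  expect_equal(back$z_m, tr$altitudes, tolerance = 1e-9)
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_identical(meta$particle, "bacterial_organelle")
  expect_identical(meta$stop_reason, "forcing_exhausted")
})
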