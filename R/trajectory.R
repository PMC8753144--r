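#' Integrate a particle's altitude through the density column
#'
#' Advances a disc particle vertically under piecewise wind forcing,
#' re-reading air density and gravity from the profile each step so that
#' multi-kilometre climbs see the (near-exponential) density gradient,
#' while coefficients are frozen within a step — the separation of
#' timescales that justifies treating the wind and density as locally
#' constant.
#'
#' Two modes:
#' * `"quasi_steady"` (default): the particle is assumed relaxed to its
#'   local steady state each step, `v = w - sqrt(g rho_p h / rho)`; valid
#'   when the relaxation time (well under a second for the built-in
#'   presets at these densities) is much shorter than the forcing
#'   timescale. Sub-threshold wind gives a negative `v`: quasi-steady
#'   descent at terminal speed relative to the air.
#' * `"full_ode"`: the signed acceleration equation is integrated
#'   numerically (via \pkg{deSolve}) with the particle starting at rest,
#'   capturing the transient spin-up.
#'
#' Forcing may be a single [wind_episode], a list of episodes in time
#' order, or a [wind_series] (each sample is held constant over its
#' sampling interval). An episode's `rho_override` pins the air density
#' for its duration. Integration stops when the forcing is exhausted or
#' the particle reaches the edge of the atmosphere table; leaving the
#' table truncates the trajectory with a recorded stop reason rather than
#' raising an error.
#'
#' @param p A [particle].
#' @param forcing A [wind_episode], list of episodes, or [wind_series].
#' @param atm An [atmosphere][standard_atmosphere].
#' @param gravity A [gravity_model].
#' @param z0 Release altitude (m), within the table span.
#' @param dt Recording/step interval (s), positive. Default 1 s.
#' @param mode `"quasi_steady"` or `"full_ode"`.
#'
#' @return An object of class `loft_trajectory`: equal-length vectors
#'   `times`, `altitudes`, `velocities`, `winds`, `densities`, plus
#'   `mode`, `stop_reason` (`"forcing_exhausted"`, `"table_floor"` or
#'   `"table_ceiling"`) and `metadata`.
#'
#' @examples
#' org <- particle_preset("bacterial_organelle")
#' tr <- integrate_trajectory(org, wind_episode(50, 1200),
#'                            standard_atmosphere(), gravity_model(),
#'                            z0 = 100e3)
#' summary(tr)
#' @export
integrate_trajectory <- function(p, forcing, atm, gravity, z0, dt = 1,
                                 mode = c("quasi_steady", "full_ode")) {
  stopifnot(inherits(p, "loft_particle"), inherits(atm, "atmosphere"),
            inherits(gravity, "gravity_model"))
  mode <- match.arg(mode)
  check_positive_scalar(dt, "dt")
  check_numeric(z0, "z0")
  check_span(atm, z0)

  segs <- normalize_forcing(forcing)
  z_lo <- atm$altitudes[1L]
  z_hi <- atm$altitudes[length(atm$altitudes)]

  n_guess <- ceiling(sum(segs$duration) / dt) + length(segs$duration) + 1L
  times <- altitudes <- velocities <- winds <- densities <- numeric(n_guess)
  k <- 0L
  push <- function(t, z, v, w, rho) {
    k <<- k + 1L
    times[k] <<- t; altitudes[k] <<- z; velocities[k] <<- v
    winds[k] <<- w; densities[k] <<- rho
  }

  t <- 0; z <- z0; v <- 0
  stop_reason <- "forcing_exhausted"

  for (i in seq_along(segs$w)) {
    w <- segs$w[i]
    rho_fix <- segs$rho_override[[i]]
    t_end <- t + segs$duration[i]
    while (t < t_end - 1e-9) {
      step <- min(dt, t_end - t)
      rho <- if (is.null(rho_fix)) density_at(atm, z) else rho_fix
      g <- gravity_at(gravity, z)
      if (mode == "quasi_steady") {
        v <- steady_state_velocity(p, rho, g, w)
        push(t, z, v, w, rho)
        z_next <- z + v * step
      } else {
        push(t, z, v, w, rho)
        out <- ode_step(p, rho, g, w, z, v, step)
        z_next <- out[1L]
        v <- out[2L]
      }
      t <- t + step
      if (z_next < z_lo || z_next > z_hi) {
        stop_reason <- if (z_next < z_lo) "table_floor" else "table_ceiling"
        z <- min(max(z_next, z_lo), z_hi)
        break
      }
      z <- z_next
    }
    if (stop_reason != "forcing_exhausted") break
  }
  # closing row at the final state
  rho <- if (!is.null(segs$rho_override[[min(i, length(segs$w))]]))
    segs$rho_override[[min(i, length(segs$w))]] else density_at(atm, z)
  g <- gravity_at(gravity, z)
  w_last <- segs$w[min(i, length(segs$w))]
  v_last <- if (mode == "quasi_steady")
    steady_state_velocity(p, rho, g, w_last) else v
  push(t, z, v_last, w_last, rho)

  structure(
    list(times = times[1:k], altitudes = altitudes[1:k],
         velocities = velocities[1:k], winds = winds[1:k],
         densities = densities[1:k], mode = mode, stop_reason = stop_reason,
         metadata = list(particle = p$label, atmosphere = atm$source_label,
                         gravity = gravity$mode, z0 = z0, dt = dt)),
    class = "loft_trajectory")
}

# integrate (z, v) over one step with frozen rho and g
ode_step <- function(p, rho, g, w, z, v, step) {
  lam <- rho / (p$rho_p * p$h)
  deriv <- function(t, y, parms) {
    rel <- w - y[2L]
    list(c(y[2L], -g + sign(rel + (rel == 0)) * lam * rel^2))
  }
  out <- deSolve::lsoda(c(z, v), c(0, step), deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  out[nrow(out), 2:3]
}

normalize_forcing <- function(forcing) {
  if (inherits(forcing, "wind_episode")) forcing <- list(forcing)
  if (inherits(forcing, "wind_series")) {
    return(list(w = forcing$winds,
                duration = rep(forcing$dt, length(forcing$winds)),
                rho_override = vector("list", length(forcing$winds))))
  }
  if (!is.list(forcing) || !all(vapply(forcing, inherits, TRUE, "wind_episode"))) {
    stop_value("`forcing` must be a wind_episode, a list of wind_episodes, or a wind_series")
  }
  list(w = vapply(forcing, `[[`, 0, "w"),
       duration = vapply(forcing, `[[`, 0, "duration"),
       rho_override = lapply(forcing, `[[`, "rho_override"))
}

#' @export
print.loft_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s, %d rows, %s\n", x$mode, length(x$times),
              x$stop_reason))
  cat(sprintf("  particle %s: z %0.f m -> %.0f m (climb %.1f m) over %.0f s\n",
              x$metadata$particle, x$altitudes[1],
              x$altitudes[length(x$altitudes)],
              x$altitudes[length(x$altitudes)] - x$altitudes[1],
              x$times[length(x$times)]))
  invisible(x)
}

#' @export
summary.loft_trajectory <- function(object, ...) {
  n <- length(object$times)
  res <- list(
    mode = object$mode, stop_reason = object$stop_reason,
    duration_s = object$times[n] - object$times[1],
    z_start_m = object$altitudes[1], z_end_m = object$altitudes[n],
    climb_m = object$altitudes[n] - object$altitudes[1],
    v_final_m_s = object$velocities[n],
    w_range_m_s = range(object$winds))
  class(res) <- "summary.loft_trajectory"
  res
}

#' @export
print.summary.loft_trajectory <- function(x, ...) {
  cat(sprintf("trajectory summary (%s, %s)\n", x$mode, x$stop_reason))
  cat(sprintf("  duration: %.0f s\n", x$duration_s))
  cat(sprintf("  altitude: %.0f -> %.0f m (climb %.1f m)\n",
              x$z_start_m, x$z_end_m, x$climb_m))
  cat(sprintf("  final particle velocity: %.3f m s-1\n", x$v_final_m_s))
  cat(sprintf("  wind range: [%.3g, %.3g] m s-1\n",
              x$w_range_m_s[1], x$w_range_m_s[2]))
  invisible(x)
}

#' @export
plot.loft_trajectory <- function(x, ...) {
  graphics::plot(x$times, x$altitudes / 1e3, type = "l",
                 xlab = "time (s)", ylab = "altitude (km)", ...)
  invisible(x)
}

#' Total climb of a trajectory
#' @param traj A `loft_trajectory`.
#' @return Net altitude change (m), final minus initial.
#' @export
climb <- function(traj) {
  stopifnot(inherits(traj, "loft_trajectory"))
  traj$altitudes[length(traj$altitudes)] - traj$altitudes[1]
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' The CSV has header `t_s,z_m,v_m_s,w_m_s,rho_kg_m3`; the sidecar
#' (`<path>.json`) records particle label, atmosphere source, mode, stop
#' reason and integration settings.
#'
#' @param traj A `loft_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "loft_trajectory"))
  df <- data.frame(t_s = traj$times, z_m = traj$altitudes,
                   v_m_s = traj$velocities, w_m_s = traj$winds,
                   rho_kg_m3 = traj$densities)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(traj$metadata, list(mode = traj$mode, stop_reason = traj$stop_reason,
                                schema_version = "1"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Ceiling altitude attainable at a given wind speed
#'
#' As a particle climbs, falling air density raises the threshold
#' velocity; ascent stalls at the altitude where the threshold equals the
#' available wind, i.e. the root of
#' `threshold_velocity(p, rho(z), g(z)) = w` on the monotone segment of
#' the profile above `z_lo` (default 70 km). The root is bracketed and
#' solved to 1 m.
#'
#' @inheritParams integrate_trajectory
#' @param w Available upward wind speed (m s-1), positive.
#' @param z_lo Lower edge of the search segment (m).
#' @param tol Root tolerance (m).
#' @return The ceiling altitude (m), with attribute `reason`:
#'   `"threshold_match"` for an interior root; `"table_ceiling"` (value =
#'   table top) when `w` exceeds the threshold over the whole segment; or
#'   `NA` with reason `"no_ceiling"` when `w` is below the threshold over
#'   the whole segment and the particle cannot ascend there at all.
#' @examples
#' ceiling_altitude(particle_preset("h1n1_virus"), w = 50,
#'                  standard_atmosphere(), gravity_model())
#' @export
ceiling_altitude <- function(p, w, atm, gravity, z_lo = 70e3, tol = 1) {
  stopifnot(inherits(p, "loft_particle"), inherits(atm, "atmosphere"),
            inherits(gravity, "gravity_model"))
  check_positive_scalar(w, "w")
  z_hi <- atm$altitudes[length(atm$altitudes)]
  if (z_lo >= z_hi) stop_value("`z_lo` must lie below the table top")
  f <- function(z) {
    threshold_velocity(p, density_at(atm, z), gravity_at(gravity, z)) - w
  }
  if (f(z_lo) >= 0) {
    return(structure(NA_real_, reason = "no_ceiling"))
  }
  if (f(z_hi) <= 0) {
    return(structure(z_hi, reason = "table_ceiling"))
  }
  root <- stats::uniroot(f, c(z_lo, z_hi), tol = tol)$root
  structure(root, reason = "threshold_match")
}

#' Horizontal excursion during a climb, with coherence check
#'
#' A particle riding an updraft for `duration` seconds is simultaneously
#' advected horizontally at the (much larger) horizontal wind speed `u`.
#' Large vertical winds along auroral arcs have been observed to stay
#' correlated over about 300 km in the horizontal, so an ascent estimate
#' is self-consistent only while the horizontal excursion `u * duration`
#' stays within that correlation length.
#'
#' @param u Horizontal wind speed (m s-1), non-negative.
#' @param duration Time aloft (s), positive.
#' @param correlation_length Coherence scale (m), default 3e5.
#' @return A list with `distance_m` and logical `within_correlation`
#'   (`TRUE` iff `distance_m <= correlation_length`).
#' @examples
#' horizontal_excursion(200, 1200)  # 240 km, within 300 km
#' @export
horizontal_excursion <- function(u, duration, correlation_length = 3e5) {
  check_nonneg_scalar(u, "u")
  check_positive_scalar(duration, "duration")
  check_positive_scalar(correlation_length, "correlation_length")
  d <- u * duration
  list(distance_m = d, within_correlation = d <= correlation_length)
}
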