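#' Run a configured transport scenario end to end
#'
#' A scenario bundles a particle, an atmosphere, a gravity convention and
#' a wind specification, integrates the trajectory and reports the
#' derived quantities of interest in one summary: threshold velocity,
#' steady-state velocity and relaxation time at the release altitude,
#' total climb, ceiling altitude for the peak wind, and (when a
#' horizontal wind is supplied) the horizontal excursion with its
#' coherence flag.
#'
#' `config` is a named list (or a path to a JSON file holding one) with
#' fields:
#' \describe{
#'   \item{particle}{a [particle], or a spec string for
#'     [parse_particle_spec()] such as `"preset:h1n1_virus"`.}
#'   \item{atmosphere}{`"embedded"` (default) or a CSV path for
#'     [atmosphere_from_file()].}
#'   \item{gravity}{`"inverse_square"` (default) or `"constant"`.}
#'   \item{wind}{a list: `type = "constant"` with `w`, `duration` and
#'     optional `rho_override`; `type = "csv"` with `path`; or
#'     `type = "synth"` with the [synthesize_wind()] parameters (a `seed`
#'     is then mandatory).}
#'   \item{z0, dt, mode}{release altitude (m), step (s, default 1) and
#'     integration mode (default `"quasi_steady"`).}
#'   \item{horizontal_wind}{optional horizontal speed (m s-1) for the
#'     excursion estimate.}
#'   \item{label}{free text naming the scenario.}
#' }
#' The configuration is validated before any computation; an invalid
#' configuration raises a single-line error.
#'
#' @param config Named list or path to a JSON config file.
#' @param out_dir Optional directory; when given, the trajectory CSV
#'   (`trajectory.csv` plus JSON sidecar) and `summary.json` are written
#'   there.
#' @return A list of class `loft_scenario_result` with elements
#'   `summary` (named list, schema version 1) and `trajectory`
#'   (a `loft_trajectory`).
#' @examples
#' res <- run_scenario(builtin_scenario("organelle_greenland"))
#' res$summary$steady_state_v_m_s   # ~13
#' @export
run_scenario <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- validate_scenario_config(config)

  atm <- if (identical(cfg$atmosphere, "embedded")) standard_atmosphere()
         else atmosphere_from_file(cfg$atmosphere)
  grav <- gravity_model(cfg$gravity)
  p <- cfg$particle
  forcing <- build_forcing(cfg$wind)

  traj <- integrate_trajectory(p, forcing, atm, grav, z0 = cfg$z0,
                               dt = cfg$dt, mode = cfg$mode)

  rho0 <- if (!is.null(cfg$wind$rho_override)) cfg$wind$rho_override
          else density_at(atm, cfg$z0)
  g0 <- gravity_at(grav, cfg$z0)
  w_peak <- max(normalize_forcing(forcing)$w)
  ceil <- ceiling_altitude(p, max(w_peak, 1e-6), atm, grav)
  n <- length(traj$times)

  summary <- list(
    schema_version = "1",
    scenario = cfg$label,
    particle = p$label,
    mode = cfg$mode,
    z0_m = cfg$z0,
    threshold_v_m_s = threshold_velocity(p, rho0, g0),
    steady_state_v_m_s = steady_state_velocity(p, rho0, g0, w_peak),
    relaxation_time_s = relaxation_time(p, rho0, g0),
    climb_m = climb(traj),
    z_final_m = traj$altitudes[n],
    duration_s = traj$times[n],
    ceiling_m = as.numeric(ceil),
    ceiling_reason = attr(ceil, "reason"),
    stop_reason = traj$stop_reason)
  if (!is.null(cfg$horizontal_wind)) {
    hx <- horizontal_excursion(cfg$horizontal_wind, summary$duration_s)
    summary$horizontal_excursion_m <- hx$distance_m
    summary$within_correlation <- hx$within_correlation
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_csv(traj, file.path(out_dir, "trajectory.csv"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  structure(list(summary = summary, trajectory = traj),
            class = "loft_scenario_result")
}

#' @export
print.loft_scenario_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<scenario> %s (%s, %s)\n", s$scenario, s$particle, s$mode))
  cat(sprintf("  threshold at z0: %.3f m s-1; steady state: %.3f m s-1\n",
              s$threshold_v_m_s, s$steady_state_v_m_s))
  cat(sprintf("  climb: %.1f m in %.0f s (stop: %s)\n", s$climb_m,
              s$duration_s, s$stop_reason))
  if (is.na(s$ceiling_m)) {
    cat("  ceiling: none within table span\n")
  } else {
    cat(sprintf("  ceiling: %.0f m (%s)\n", s$ceiling_m, s$ceiling_reason))
  }
  invisible(x)
}

validate_scenario_config <- function(config) {
  if (!is.list(config)) stop_value("scenario config must be a named list")
  cfg <- config
  cfg$atmosphere <- cfg$atmosphere %||% "embedded"
  cfg$gravity <- cfg$gravity %||% "inverse_square"
  cfg$dt <- cfg$dt %||% 1
  cfg$mode <- cfg$mode %||% "quasi_steady"
  cfg$label <- cfg$label %||% "unnamed"
  if (is.null(cfg$particle)) stop_value("scenario config: `particle` is required")
  if (is.character(cfg$particle)) cfg$particle <- parse_particle_spec(cfg$particle)
  if (!inherits(cfg$particle, "loft_particle")) {
    stop_value("scenario config: `particle` must be a particle or spec string")
  }
  if (is.null(cfg$z0)) stop_value("scenario config: `z0` is required")
  check_positive_scalar(cfg$z0, "z0")
  check_positive_scalar(cfg$dt, "dt")
  if (!cfg$mode %in% c("quasi_steady", "full_ode")) {
    stop_value("scenario config: `mode` must be quasi_steady or full_ode")
  }
  if (!cfg$gravity %in% c("inverse_square", "constant")) {
    stop_value("scenario config: `gravity` must be inverse_square or constant")
  }
  if (!identical(cfg$atmosphere, "embedded") && !file.exists(cfg$atmosphere)) {
    stop_value(sprintf("scenario config: atmosphere file not found: %s",
                       cfg$atmosphere))
  }
  w <- cfg$wind
  if (is.null(w) || is.null(w$type)) {
    stop_value("scenario config: `wind` with a `type` is required")
  }
  if (w$type == "constant") {
    check_numeric(w$w, "wind$w")
    check_positive_scalar(w$duration, "wind$duration")
  } else if (w$type == "csv") {
    if (is.null(w$path) || !file.exists(w$path)) {
      stop_value("scenario config: wind CSV not found")
    }
  } else if (w$type == "synth") {
    if (!is.null(w$noise_sd) && w$noise_sd > 0 && is.null(w$seed)) {
      stop_value("scenario config: synthetic wind with noise requires `seed`")
    }
  } else {
    stop_value(sprintf("scenario config: unknown wind type '%s'", w$type))
  }
  if (!is.null(cfg$horizontal_wind)) {
    check_nonneg_scalar(cfg$horizontal_wind, "horizontal_wind")
  }
  cfg
}

build_forcing <- function(wind) {
  switch(wind$type,
    constant = wind_episode(wind$w, wind$duration,
                            rho_override = wind$rho_override),
    csv = {
      s <- read_wind_csv(wind$path)
      if (length(s$winds) == 0L) stop_value("wind series is empty")
      s
    },
    synth = do.call(synthesize_wind,
                    wind[intersect(names(wind),
                                   names(formals(synthesize_wind)))]))
}

#' Built-in scenarios
#'
#' Ready-made configurations for the two worked desk estimates:
#' \describe{
#'   \item{`organelle_greenland`}{the bacterial-organelle disc released at
#'     100 km into a constant 50 m s-1 updraft for 20 min, quasi-steady:
#'     steady-state ascent ~13 m s-1.}
#'   \item{`virus_arc`}{the H1N1-sized disc riding a 50 m s-1 updraft
#'     along an auroral arc for 1 h with the air density pinned at
#'     9e-8 kg m-3 (the 110--120 km band), full-ODE: ascent ~2.5 m s-1,
#'     climb ~9 km.}
#' }
#'
#' @param name `"organelle_greenland"` or `"virus_arc"`.
#' @return A config list for [run_scenario()].
#' @examples
#' names(builtin_scenario("virus_arc"))
#' @export
builtin_scenario <- function(name) {
  scenarios <- list(
    organelle_greenland = list(
      label = "organelle_greenland",
      particle = "preset:bacterial_organelle",
      wind = list(type = "constant", w = 50, duration = 1200),
      z0 = 100e3, dt = 1, mode = "quasi_steady",
      horizontal_wind = 200),
    virus_arc = list(
      label = "virus_arc",
      particle = "preset:h1n1_virus",
      wind = list(type = "constant", w = 50, duration = 3600,
                  rho_override = 9e-8),
      z0 = 110e3, dt = 1, mode = "full_ode"))
  if (!name %in% names(scenarios)) {
    stop_value(sprintf("unknown scenario '%s'; valid: %s", name,
                       paste(names(scenarios), collapse = ", ")))
  }
  scenarios[[name]]
}

#' @rdname builtin_scenario
#' @export
builtin_scenarios <- function() c("organelle_greenland", "virus_arc")

#' Threshold-velocity table across altitude for a set of particles
#'
#' Evaluates the threshold (minimum sustaining) wind speed on an altitude
#' grid for each particle — the curves that show which winds can loft
#' which archetypes where. Above ~70 km the threshold rises monotonically
#' with altitude as density falls.
#'
#' @param particles List of [particle]s (default: the three presets).
#' @param z_from,z_to,step Altitude grid (m).
#' @inheritParams integrate_trajectory
#' @return A data.frame with column `z_m` and one threshold column
#'   (m s-1) per particle label.
#' @examples
#' head(report_thresholds(z_from = 90e3, z_to = 120e3, step = 10e3))
#' @export
report_thresholds <- function(particles = lapply(particle_presets(),
                                                 particle_preset),
                              z_from = 70e3, z_to = 150e3, step = 1e3,
                              atm = standard_atmosphere(),
                              gravity = gravity_model()) {
  stopifnot(is.list(particles), length(particles) > 0)
  z <- seq(z_from, z_to, by = step)
  check_span(atm, z)
  rho <- density_at(atm, z)
  g <- gravity_at(gravity, z)
  out <- data.frame(z_m = z)
  for (p in particles) {
    stopifnot(inherits(p, "loft_particle"))
    out[[p$label]] <- threshold_velocity(p, rho, g)
  }
  out
}
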