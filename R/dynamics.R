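#' Forces and velocities of a disc in a directed vertical flow
#'
#' Core model equations. A disc of column density `rho_p * h` facing a
#' vertical wind `w` while moving at velocity `v` (both signed, up
#' positive) obeys
#'
#'   dv/dt = -g + H(w - v) * (rho / (rho_p * h)) * (w - v)^2,
#'
#' where `rho` is the local air density and `H` is a sign function (+1 for
#' positive relative wind, -1 for negative) that keeps the quadratic
#' momentum-flux force pointing with the relative wind. The drag
#' coefficient is unity: the force magnitude is the stagnation pressure
#' `rho * (w - v)^2` times the disc area. Writing `lambda = rho / (rho_p h)`
#' (units m-1), the model has
#'
#'  * threshold (terminal) velocity `sqrt(g / lambda) = sqrt(g rho_p h / rho)`,
#'    the minimum upward wind that balances the weight;
#'  * steady-state particle velocity `w - sqrt(g / lambda)` (negative for
#'    sub-threshold wind: quasi-steady descent at terminal speed relative
#'    to the air);
#'  * relaxation timescale `1 / sqrt(lambda g)` for the approach to the
#'    steady state;
#'  * the closed-form transient from rest, implemented in
#'    [transient_velocity()].
#'
#' @param p A [particle].
#' @param rho Local air density (kg m-3).
#' @param g Local gravitational acceleration (m s-2).
#' @param w Vertical wind speed (m s-1, up positive).
#' @param v Particle velocity (m s-1, up positive).
#' @param r Disc radius (m).
#'
#' @return `wind_force()` the signed vertical force (N) of the wind on a
#'   disc of radius `r`; `particle_acceleration()` the signed acceleration
#'   (m s-2); `threshold_velocity()`, `steady_state_velocity()` velocities
#'   (m s-1); `relaxation_time()` a time (s).
#'
#' @examples
#' org <- particle_preset("bacterial_organelle")
#' g <- gravity_at(gravity_model(), 100e3)
#' steady_state_velocity(org, rho = 5.604e-7, g = g, w = 50)  # ~13 m s-1
#' threshold_velocity(org, rho = 5.604e-7, g = g)             # ~37 m s-1
#' @name dynamics
NULL

heaviside_sign <- function(x) ifelse(x < 0, -1, 1)

#' @rdname dynamics
#' @export
wind_force <- function(rho, r, w, v) {
  check_numeric(rho, "rho"); check_numeric(w, "w"); check_numeric(v, "v")
  if (any(rho < 0)) stop_value("air density `rho` must be non-negative")
  check_positive_scalar(r, "r")
  rel <- w - v
  heaviside_sign(rel) * rho * pi * r^2 * rel^2
}

#' @rdname dynamics
#' @export
particle_acceleration <- function(p, rho, g, w, v) {
  stopifnot(inherits(p, "loft_particle"))
  check_numeric(rho, "rho"); check_numeric(g, "g")
  check_numeric(w, "w"); check_numeric(v, "v")
  if (any(rho < 0)) stop_value("air density `rho` must be non-negative")
  rel <- w - v
  -g + heaviside_sign(rel) * (rho / (p$rho_p * p$h)) * rel^2
}

#' @rdname dynamics
#' @export
threshold_velocity <- function(p, rho, g) {
  stopifnot(inherits(p, "loft_particle"))
  check_numeric(rho, "rho"); check_numeric(g, "g")
  if (any(rho <= 0)) stop_value("air density `rho` must be positive")
  sqrt(g * p$rho_p * p$h / rho)
}

#' @rdname dynamics
#' @export
steady_state_velocity <- function(p, rho, g, w) {
  check_numeric(w, "w")
  w - threshold_velocity(p, rho, g)
}

#' @rdname dynamics
#' @export
relaxation_time <- function(p, rho, g) {
  stopifnot(inherits(p, "loft_particle"))
  check_numeric(rho, "rho"); check_numeric(g, "g")
  if (any(rho <= 0)) stop_value("air density `rho` must be positive")
  lambda <- rho / (p$rho_p * p$h)
  1 / sqrt(lambda * g)
}

#' Closed-form transient velocity of a particle released at rest
#'
#' Solution of the separable ascent equation for a particle starting from
#' rest in a constant super-threshold upward wind `w` with air density and
#' gravity frozen:
#'
#'   v(t) = w - sqrt(g/lambda) * (1 + A e^(-2 t sqrt(lambda g))) /
#'                               (1 - A e^(-2 t sqrt(lambda g))),
#'
#'   A = (sqrt(lambda/g) w - 1) / (sqrt(lambda/g) w + 1),
#'   lambda = rho / (rho_p h).
#'
#' It satisfies v(0) = 0, increases monotonically, and approaches but
#' never reaches the steady state `w - sqrt(g/lambda)` (hence never the
#' wind speed itself). The form assumes ascent, so `w` must exceed the
#' threshold velocity; outside that domain the function errors rather
#' than extrapolate.
#'
#' @inheritParams dynamics
#' @param t Time since release (s), non-negative; vectorised.
#' @return Velocity (m s-1) at each `t`.
#' @examples
#' org <- particle_preset("bacterial_organelle")
#' transient_velocity(org, rho = 5.604e-7, g = 9.51, w = 50,
#'                    t = c(0, 1, 10))
#' @export
transient_velocity <- function(p, rho, g, w, t) {
  stopifnot(inherits(p, "loft_particle"))
  check_positive_scalar(rho, "rho"); check_positive_scalar(g, "g")
  check_numeric(t, "t")
  if (any(t < 0)) stop_value("time `t` must be non-negative")
  wth <- threshold_velocity(p, rho, g)
  if (!is.numeric(w) || length(w) != 1L || w <= wth) {
    stop_value(sprintf(
      "transient solution requires w above the threshold velocity (%.4g m s-1)",
      wth))
  }
  lambda <- rho / (p$rho_p * p$h)
  s <- sqrt(lambda / g)                  # 1 / threshold velocity
  A <- (s * w - 1) / (s * w + 1)
  E <- exp(-2 * t * sqrt(lambda * g))
  w - (1 / s) * (1 + A * E) / (1 - A * E)
}

#' Derived drag quantities for a particle in given air
#'
#' Bundles the signed drag parameter `lambda = H * rho / (rho_p h)`, the
#' separable-form parameter `b = lambda / g`, the sign factor `H` of the
#' relative wind, and the local threshold, steady-state velocity and
#' relaxation time.
#'
#' @inheritParams dynamics
#' @return A list of class `dynamics_context` with fields `lambda`, `b`,
#'   `H`, `g`, `rho`, `threshold`, `v_steady`, `tau`.
#' @examples
#' dynamics_context(particle_preset("standard_dust"),
#'                  rho = 5.604e-7, g = 9.51, w = 50)
#' @export
dynamics_context <- function(p, rho, g, w, v = 0) {
  stopifnot(inherits(p, "loft_particle"))
  check_positive_scalar(rho, "rho"); check_positive_scalar(g, "g")
  H <- heaviside_sign(w - v)
  lambda <- H * rho / (p$rho_p * p$h)
  structure(list(lambda = lambda, b = lambda / g, H = H, g = g, rho = rho,
                 threshold = threshold_velocity(p, rho, g),
                 v_steady = steady_state_velocity(p, rho, g, w),
                 tau = relaxation_time(p, rho, g)),
            class = "dynamics_context")
}

#' @export
print.dynamics_context <- function(x, ...) {
  cat("<dynamics_context>\n")
  cat(sprintf("  lambda = %.4g m-1 (H = %+d), threshold = %.4g m s-1\n",
              x$lambda, x$H, x$threshold))
  cat(sprintf("  v_steady = %.4g m s-1, relaxation time = %.4g s\n",
              x$v_steady, x$tau))
  invisible(x)
}
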