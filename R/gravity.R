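#' Gravitational acceleration vs altitude
#'
#' A `gravity_model` evaluates g(z) either as inverse-square gravity
#' g0 * (R / (R + z))^2 above a spherical Earth (the default, which the
#' worked altitude estimates in this package assume) or as the constant
#' surface value g0. Over the 90--200 km band the two differ by up to
#' about 0.6 m s-2, enough to move steady-state ascent rates by a few
#' tenths of a metre per second.
#'
#' @param mode `"inverse_square"` or `"constant"`.
#' @param g0 Surface standard gravity (m s-2).
#' @param earth_radius Mean Earth radius (m).
#' @param model A `gravity_model`.
#' @param z Geometric altitude (m), non-negative; vectorised.
#'
#' @return `gravity_model()` an object of class `gravity_model`;
#'   `gravity_at()` the local acceleration (m s-2).
#'
#' @examples
#' g <- gravity_model()
#' gravity_at(g, 0)      # 9.80665
#' gravity_at(g, 100e3)  # ~9.51
#' @export
gravity_model <- function(mode = c("inverse_square", "constant"),
                          g0 = 9.80665, earth_radius = 6.371e6) {
  mode <- match.arg(mode)
  check_positive_scalar(g0, "g0")
  check_positive_scalar(earth_radius, "earth_radius")
  structure(list(mode = mode, g0 = g0, earth_radius = earth_radius),
            class = "gravity_model")
}

#' @rdname gravity_model
#' @export
gravity_at <- function(model, z) {
  stopifnot(inherits(model, "gravity_model"))
  check_numeric(z, "z")
  if (any(z < 0)) stop_value("altitude `z` must be non-negative")
  if (model$mode == "constant") {
    return(rep_len(model$g0, length(z)))
  }
  R <- model$earth_radius
  model$g0 * (R / (R + z))^2
}

#' @export
print.gravity_model <- function(x, ...) {
  cat(sprintf("<gravity_model> %s, g0 = %g m s-2\n", x$mode, x$g0))
  invisible(x)
}
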