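#' Vertical wind forcing: episodes and time series
#'
#' Two representations of the vertical wind drive trajectory integration.
#' A `wind_episode` is a constant wind `w` held for `duration` seconds —
#' the piecewise-constant idealisation under which the closed-form
#' solutions hold — optionally with a fixed air density `rho_override`
#' (used to reproduce constant-density updraft estimates along an auroral
#' arc). A `wind_series` is a uniformly sampled signed time series `w(t)`
#' such as an instrument record or the output of [synthesize_wind()].
#'
#' @param w Vertical wind speed (m s-1, up positive).
#' @param duration Episode length (s), positive.
#' @param rho_override Optional fixed air density (kg m-3) used instead of
#'   the atmosphere profile while this episode lasts.
#' @param times,winds Equal-length numeric vectors; `times` strictly
#'   increasing with a uniform step (relative tolerance 1e-6).
#' @param z_ref Reference altitude (m) recorded as metadata.
#' @param provenance Free text describing where the series came from.
#'
#' @return `wind_episode()` an object of class `wind_episode`;
#'   `wind_series()` an object of class `wind_series`.
#' @examples
#' wind_episode(50, duration = 1200)
#' wind_series(times = 0:9, winds = rep(20, 10))
#' @export
wind_episode <- function(w, duration, rho_override = NULL, z_ref = NA_real_) {
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w))
  check_positive_scalar(duration, "duration")
  if (!is.null(rho_override)) check_positive_scalar(rho_override, "rho_override")
  structure(list(w = w, duration = duration, rho_override = rho_override,
                 z_ref = z_ref),
            class = "wind_episode")
}

#' @rdname wind_episode
#' @export
wind_series <- function(times, winds, z_ref = NA_real_, provenance = "user") {
  check_numeric(times, "times")
  check_numeric(winds, "winds")
  if (length(times) != length(winds)) {
    stop_value("`times` and `winds` must have equal length")
  }
  if (length(times) < 2L) stop_value("a wind series needs at least two samples")
  dt <- diff(times)
  if (any(dt <= 0)) {
    stop_value(sprintf("`times` must be strictly increasing (first violation at sample %d)",
                       which(dt <= 0)[1L] + 1L))
  }
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) {
    stop_value("`times` must be uniformly spaced")
  }
  structure(list(times = as.numeric(times), winds = as.numeric(winds),
                 dt = mean(dt), z_ref = z_ref, provenance = provenance),
            class = "wind_series")
}

#' @export
print.wind_series <- function(x, ...) {
  cat(sprintf("<wind_series> %d samples, dt = %g s, w in [%.3g, %.3g] m s-1\n",
              length(x$times), x$dt, min(x$winds), max(x$winds)))
  cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

#' @export
plot.wind_series <- function(x, ...) {
  graphics::plot(x$times, x$winds, type = "l",
                 xlab = "time (s)", ylab = "vertical wind (m s-1)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Seeded generator of oscillatory vertical-wind series
#'
#' Emulates the qualitative structure of observed thermospheric vertical
#' winds — oscillation between upward and downward phases with magnitudes
#' of tens of m s-1 over tens of minutes — as a sinusoid plus an optional
#' mean offset and Gaussian noise:
#'
#'   w(t) = mean_offset + amplitude * sin(2 pi t / period) + N(0, noise_sd).
#'
#' The series is sampled at step `dt` on `[0, duration)` and is exactly
#' reproducible for a fixed `seed`. An optional list of `harmonics`
#' (each `list(amplitude, period, phase)`) adds further sinusoids for
#' richer spectra.
#'
#' @param amplitude Sinusoid amplitude (m s-1), non-negative.
#' @param period Oscillation period (s), positive.
#' @param noise_sd Standard deviation of additive Gaussian noise (m s-1).
#' @param mean_offset Constant offset (m s-1).
#' @param duration Series length (s), at least `dt`.
#' @param dt Sampling step (s), positive.
#' @param seed Integer seed; required when `noise_sd > 0` for
#'   reproducibility.
#' @param z_ref Reference altitude (m), metadata only.
#' @param harmonics Optional list of extra sinusoid components.
#' @return A [wind_series].
#' @examples
#' ws <- synthesize_wind(amplitude = 30, period = 1800, noise_sd = 5,
#'                       mean_offset = 10, duration = 7200, dt = 10,
#'                       seed = 42)
#' range(ws$winds)
#' @export
synthesize_wind <- function(amplitude = 30, period = 1800, noise_sd = 0,
                            mean_offset = 10, duration = 7200, dt = 10,
                            seed = NULL, z_ref = 103e3, harmonics = NULL) {
  check_nonneg_scalar(amplitude, "amplitude")
  check_positive_scalar(period, "period")
  check_nonneg_scalar(noise_sd, "noise_sd")
  check_positive_scalar(dt, "dt")
  check_positive_scalar(duration, "duration")
  if (duration < dt) stop_value("`duration` must be at least `dt`")
  t <- seq(0, duration - dt, by = dt)
  w <- mean_offset + amplitude * sin(2 * pi * t / period)
  for (hm in harmonics) {
    w <- w + hm$amplitude * sin(2 * pi * t / hm$period + (hm$phase %||% 0))
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop_value("`seed` is required when `noise_sd` > 0")
    # keep the generator state local to this call
    old <- .Random.seed_exists()
    set.seed(as.integer(seed))
    w <- w + stats::rnorm(length(t), 0, noise_sd)
    .restore_seed(old)
  }
  prov <- sprintf(
    "synthesize_wind(amplitude=%g, period=%g, noise_sd=%g, mean_offset=%g, duration=%g, dt=%g, seed=%s)",
    amplitude, period, noise_sd, mean_offset, duration, dt,
    if (is.null(seed)) "NULL" else as.character(seed))
  wind_series(t, w, z_ref = z_ref, provenance = prov)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Read and write vertical-wind CSV files
#'
#' The on-disk dialect is a comma-separated UTF-8 file with header
#' `t_s,w_m_s`: time in seconds (strictly increasing, uniform step) and
#' signed vertical wind in m s-1. `read_wind_csv()` validates the file and
#' reports the first offending line on error; `write_wind_csv()` writes a
#' [wind_series] so that a read/write round trip preserves values to
#' better than 1e-9 relative.
#'
#' @param path File path.
#' @param series A [wind_series].
#' @return `read_wind_csv()` a [wind_series]; `write_wind_csv()` the path,
#'   invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_wind_csv(wind_series(0:5, c(5, 10, 20, 15, 5, -5)), f)
#' read_wind_csv(f)
#' @export
read_wind_csv <- function(path) {
  if (!file.exists(path)) stop_value(sprintf("wind file not found: %s", path))
  tab <- tryCatch(utils::read.csv(path, colClasses = "numeric"),
                  error = function(e) {
                    stop_value(sprintf("cannot parse wind CSV %s: %s",
                                       path, conditionMessage(e)))
                  })
  if (!all(c("t_s", "w_m_s") %in% names(tab))) {
    stop_value(sprintf("wind CSV %s must have columns t_s,w_m_s", path))
  }
  if (nrow(tab) < 2L) {
    stop_value(sprintf("wind CSV %s has fewer than two samples", path))
  }
  if (anyNA(tab$t_s) || anyNA(tab$w_m_s)) {
    bad <- which(is.na(tab$t_s) | is.na(tab$w_m_s))[1L]
    stop_value(sprintf("unparseable value in %s at data line %d", path, bad))
  }
  dt <- diff(tab$t_s)
  if (any(dt <= 0)) {
    stop_value(sprintf("time not strictly increasing in %s at data line %d",
                       path, which(dt <= 0)[1L] + 1L))
  }
  wind_series(tab$t_s, tab$w_m_s, provenance = path)
}

#' @rdname read_wind_csv
#' @export
write_wind_csv <- function(series, path) {
  stopifnot(inherits(series, "wind_series"))
  df <- data.frame(t_s = format(series$times, digits = 15, trim = TRUE,
                                scientific = FALSE),
                   w_m_s = format(series$winds, digits = 15, trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Segment a wind series into constant-wind episodes
#'
#' Splits a [wind_series] into maximal runs of samples at or above
#' `threshold` (ascent candidates) and runs below it. Each run becomes a
#' [wind_episode] whose speed is the run mean — a conservative choice,
#' matching the use of an average ascent speed in climb estimates — and
#' whose duration is the run length times the sampling step, so episode
#' durations sum exactly to the series duration `n * dt`.
#'
#' @param series A [wind_series].
#' @param threshold Split level (m s-1), non-negative.
#' @return A list of [wind_episode] objects, in time order, each with an
#'   `above` attribute flagging whether its run was at or above the
#'   threshold.
#' @examples
#' ws <- synthesize_wind(amplitude = 30, mean_offset = 10, noise_sd = 0,
#'                       duration = 3600, dt = 10)
#' length(episodes_from_series(ws, threshold = 20))
#' @export
episodes_from_series <- function(series, threshold = 0) {
  stopifnot(inherits(series, "wind_series"))
  check_nonneg_scalar(threshold, "threshold")
  if (length(series$winds) == 0L) stop_value("empty wind series")
  above <- series$winds >= threshold
  runs <- rle(above)
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  out <- vector("list", length(runs$lengths))
  for (i in seq_along(runs$lengths)) {
    sel <- idx_start[i]:idx_end[i]
    ep <- wind_episode(mean(series$winds[sel]),
                       duration = runs$lengths[i] * series$dt,
                       z_ref = series$z_ref)
    attr(ep, "above") <- runs$values[i]
    out[[i]] <- ep
  }
  out
}
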