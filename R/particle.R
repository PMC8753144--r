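#' Disc-shaped test particles
#'
#' The model's test particle is a thin disc of radius `r` and thickness
#' `h` that always faces the vertical wind broadside, with drag
#' coefficient fixed at unity. Its bulk density is rho_p = m / (pi r^2 h).
#' `particle()` accepts any three of mass `m`, radius `r`, thickness `h`
#' and density `rho_p` and derives the fourth; if all four are supplied
#' they must be consistent to a relative tolerance of 1e-12.
#'
#' `particle_from_mass()` and `particle_from_density()` are explicit
#' spellings of the two common constructions.
#'
#' @param m Mass (kg).
#' @param r Disc radius (m).
#' @param h Disc thickness (m).
#' @param rho_p Bulk density (kg m-3).
#' @param label Free-text name carried through outputs.
#'
#' @return An object of class `loft_particle` with fields `m`, `r`, `h`,
#'   `rho_p`, `label` (SI units).
#'
#' @examples
#' # H1N1-sized virion: mass 0.8 fg, radius and thickness both 109 nm
#' particle_from_mass(0.8e-18, 109e-9, 109e-9)$rho_p   # ~196.6 kg m-3
#' # nanometre dust grain of density 1000 kg m-3
#' particle_from_density(1000, 1e-9, 1e-9)$m           # ~3.14e-24 kg
#' @export
particle <- function(m = NULL, r = NULL, h = NULL, rho_p = NULL,
                     label = "custom") {
  given <- !vapply(list(m, r, h, rho_p), is.null, logical(1))
  if (sum(given) < 3L) {
    stop_value("supply at least three of `m`, `r`, `h`, `rho_p`")
  }
  for (nm in c("m", "r", "h", "rho_p")) {
    v <- get(nm)
    if (!is.null(v)) check_positive_scalar(v, nm)
  }
  if (is.null(m)) m <- rho_p * pi * r^2 * h
  if (is.null(rho_p)) rho_p <- m / (pi * r^2 * h)
  if (is.null(h)) h <- m / (rho_p * pi * r^2)
  if (is.null(r)) r <- sqrt(m / (rho_p * pi * h))
  if (abs(m - rho_p * pi * r^2 * h) > 1e-12 * m) {
    stop_value("inconsistent particle: m != rho_p * pi * r^2 * h")
  }
  structure(list(m = m, r = r, h = h, rho_p = rho_p, label = label),
            class = "loft_particle")
}

#' @rdname particle
#' @export
particle_from_mass <- function(m, r, h, label = "custom") {
  particle(m = m, r = r, h = h, label = label)
}

#' @rdname particle
#' @export
particle_from_density <- function(rho_p, r, h, label = "custom") {
  particle(rho_p = rho_p, r = r, h = h, label = label)
}

# archetypes, parameterised as in the threshold-curve comparison:
# the virion uses thickness = radius = the quoted 109 nm diameter, which is
# what recovers ~196 kg m-3 from the 0.8 fg mass
.particle_presets <- list(
  standard_dust      = list(rho_p = 1000, r = 1e-9,   h = 1e-9),
  h1n1_virus         = list(m = 0.8e-18,  r = 109e-9, h = 109e-9),
  bacterial_organelle = list(rho_p = 2000, r = 2e-6,  h = 40e-9)
)

#' Built-in particle archetypes
#'
#' Three presets spanning the size range of interest: `standard_dust`, a
#' nanometre dust grain (density 1000 kg m-3, r = h = 1 nm, mass ~3e-24 kg);
#' `h1n1_virus`, an H1N1-sized virion (mass 0.8 fg, r = h = 109 nm, density
#' ~196 kg m-3 -- the disc thickness is deliberately set equal to the quoted
#' diameter, the convention under which that density follows from the mass);
#' and `bacterial_organelle`, a small bacterium or organelle fragment
#' (density 2000 kg m-3, radius 2 um, thickness 40 nm, mass ~1e-15 kg).
#'
#' @param name One of `"standard_dust"`, `"h1n1_virus"`,
#'   `"bacterial_organelle"`.
#' @return A [particle].
#' @examples
#' particle_preset("bacterial_organelle")$m  # ~1e-15 kg
#' @export
particle_preset <- function(name) {
  if (length(name) != 1L || !name %in% names(.particle_presets)) {
    stop_value(sprintf("unknown preset '%s'; valid presets: %s",
                       paste(name, collapse = ","),
                       paste(names(.particle_presets), collapse = ", ")))
  }
  spec <- .particle_presets[[name]]
  do.call(particle, c(spec, list(label = name)))
}

#' @rdname particle_preset
#' @export
particle_presets <- function() names(.particle_presets)

#' Parse a particle specification string
#'
#' Accepts either `"preset:<name>"` or a comma-separated list of
#' `key=value` pairs with keys `m`, `r`, `h`, `rho` and optional length
#' unit suffixes `nm`, `um`, `mm`, `m` (mass in kg, density in kg m-3),
#' e.g. `"r=2um,h=40nm,rho=2000"`. Used by the command-line interface.
#'
#' @param spec Specification string.
#' @return A [particle].
#' @examples
#' parse_particle_spec("preset:h1n1_virus")
#' parse_particle_spec("r=2um,h=40nm,rho=2000")
#' @export
parse_particle_spec <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1L)
  if (startsWith(spec, "preset:")) {
    return(particle_preset(sub("^preset:", "", spec)))
  }
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  args <- list()
  for (p in parts) {
    kv <- strsplit(trimws(p), "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop_value(sprintf("cannot parse particle term '%s'", p))
    key <- switch(kv[1], m = "m", r = "r", h = "h", rho = "rho_p",
                  rho_p = "rho_p",
                  stop_value(sprintf("unknown particle key '%s'", kv[1])))
    args[[key]] <- parse_length(kv[2], allow_unit = key %in% c("r", "h"))
  }
  do.call(particle, c(args, list(label = spec)))
}

parse_length <- function(s, allow_unit = TRUE) {
  s <- trimws(s)
  mult <- 1
  if (allow_unit) {
    if (grepl("nm$", s)) { mult <- 1e-9; s <- sub("nm$", "", s) }
    else if (grepl("um$", s)) { mult <- 1e-6; s <- sub("um$", "", s) }
    else if (grepl("mm$", s)) { mult <- 1e-3; s <- sub("mm$", "", s) }
    else if (grepl("m$", s)) { s <- sub("m$", "", s) }
  }
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop_value(sprintf("cannot parse numeric value '%s'", s))
  v * mult
}

#' @export
print.loft_particle <- function(x, ...) {
  cat(sprintf("<particle> %s\n", x$label))
  cat(sprintf("  r = %.4g m, h = %.4g m, rho_p = %.4g kg m-3, m = %.4g kg\n",
              x$r, x$h, x$rho_p, x$m))
  cat(sprintf("  column density rho_p*h = %.4g kg m-2\n", x$rho_p * x$h))
  invisible(x)
}
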