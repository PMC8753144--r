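# Independent fixed-step RK4 integration of the signed ascent equation
#   dv/dt = -g + sign(w - v) * (rho / (rho_p h)) * (w - v)^2
# from rest, used as the oracle for the closed-form transient solution.
# Deliberately not written in terms of any package internals.
rk4_velocity <- function(rho_p, h, rho, g, w, t_end, n_steps = 2000L) {
  lam <- rho / (rho_p * h)
  f <- function(v) {
    rel <- w - v
    s <- if (rel < 0) -1 else 1
    -g + s * lam * rel^2
  }
  v <- 0
  dt <- t_end / n_steps
  for (i in seq_len(n_steps)) {
    k1 <- f(v)
    k2 <- f(v + dt * k1 / 2)
    k3 <- f(v + dt * k2 / 2)
    k4 <- f(v + dt * k3)
    v <- v + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  v
}

# constant-density atmosphere (two nodes, equal values: log-linear
# interpolation returns the constant everywhere) for tests that need the
# column frozen
const_atmosphere <- function(rho, T = 200, mfp = 0.02,
                             z = c(0, 200e3)) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(z_m = z, rho_kg_m3 = rho, T_K = T, mfp_m = mfp),
                   f, row.names = FALSE, quote = FALSE)
  atmosphere_from_file(f, source_label = "constant-test")
}
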