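# Build the packaged US Standard Atmosphere 1976 table
# (inst/extdata/ussa1976.csv): geometric altitude, air density, kinetic
# temperature and equilibrium mean free path, 0-200 km.
#
# Below 86 km the profile is computed from the standard's seven
# piecewise-linear geopotential temperature layers and the hydrostatic
# relation. From 86 km upward, where the standard switches to species
# number-density integration, the standard's published values for T, rho
# and mean molecular weight are embedded directly. Mean free path is
# computed everywhere from number density with the standard's effective
# collision diameter (3.65e-10 m).
#
# Run from the repository root:  Rscript tools/make_atmosphere_table.R

g0 <- 9.80665          # m s-2
Rstar <- 8.31432       # J mol-1 K-1 (USSA76 value)
M0 <- 28.9644e-3       # kg mol-1, mean molecular weight below 86 km
NA_ <- 6.022169e23     # mol-1 (USSA76 value)
r0 <- 6356.766e3       # m, effective Earth radius for geopotential conversion
d_coll <- 3.65e-10     # m, effective collision diameter
P0 <- 101325           # Pa

mfp_from_n <- function(n) 1 / (sqrt(2) * pi * d_coll^2 * n)

# -- layers below 86 km (geopotential base altitude km', base T, lapse K/km') --
hb <- c(0, 11, 20, 32, 47, 51, 71) * 1e3
Tb <- c(288.15, 216.65, 216.65, 228.65, 270.65, 270.65, 214.65)
Lb <- c(-6.5, 0, 1.0, 2.8, 0, -2.8, -2.0) * 1e-3

# base pressures by recursion
Pb <- numeric(7)
Pb[1] <- P0
for (i in 2:7) {
  dh <- hb[i] - hb[i - 1]
  if (Lb[i - 1] == 0) {
    Pb[i] <- Pb[i - 1] * exp(-g0 * M0 * dh / (Rstar * Tb[i - 1]))
  } else {
    Pb[i] <- Pb[i - 1] *
      (Tb[i - 1] / (Tb[i - 1] + Lb[i - 1] * dh))^(g0 * M0 / (Rstar * Lb[i - 1]))
  }
}

lower_atmo <- function(z) {  # z geometric m, returns T, rho, mfp
  h <- r0 * z / (r0 + z)
  i <- findInterval(h, hb)
  Tz <- Tb[i] + Lb[i] * (h - hb[i])
  if (Lb[i] == 0) {
    P <- Pb[i] * exp(-g0 * M0 * (h - hb[i]) / (Rstar * Tb[i]))
  } else {
    P <- Pb[i] * (Tb[i] / Tz)^(g0 * M0 / (Rstar * Lb[i]))
  }
  rho <- P * M0 / (Rstar * Tz)
  n <- rho * NA_ / M0
  c(T = Tz, rho = rho, mfp = mfp_from_n(n))
}

z_lo <- seq(0, 84, by = 2) * 1e3
lo <- t(vapply(z_lo, lower_atmo, c(T = 0, rho = 0, mfp = 0)))

# -- 86-200 km: published USSA76 values (z km, T K, rho kg m-3, M g mol-1) --
hi_tab <- matrix(c(
   86, 186.87, 6.958e-6, 28.95,
   90, 186.87, 3.416e-6, 28.91,
   95, 188.42, 1.393e-6, 28.73,
  100, 195.08, 5.604e-7, 28.40,
  105, 208.84, 2.325e-7, 27.88,
  110, 240.00, 9.708e-8, 27.27,
  115, 300.00, 4.289e-8, 26.68,
  120, 360.00, 2.222e-8, 26.20,
  130, 469.27, 8.152e-9, 25.44,
  140, 559.63, 3.831e-9, 24.75,
  150, 634.39, 2.076e-9, 24.10,
  160, 696.29, 1.233e-9, 23.49,
  170, 747.57, 7.815e-10, 22.93,
  180, 790.07, 5.194e-10, 22.50,
  190, 825.31, 3.581e-10, 22.00,
  200, 854.56, 2.541e-10, 21.50
), ncol = 4, byrow = TRUE)

n_hi <- hi_tab[, 3] * NA_ / (hi_tab[, 4] * 1e-3)
hi <- data.frame(z_m = hi_tab[, 1] * 1e3, rho_kg_m3 = hi_tab[, 3],
                 T_K = hi_tab[, 2], mfp_m = mfp_from_n(n_hi))

tab <- rbind(
  data.frame(z_m = z_lo, rho_kg_m3 = signif(lo[, "rho"], 6),
             T_K = round(lo[, "T"], 3), mfp_m = signif(lo[, "mfp"], 6)),
  data.frame(z_m = hi$z_m, rho_kg_m3 = hi$rho_kg_m3,
             T_K = hi$T_K, mfp_m = signif(hi$mfp_m, 6))
)

stopifnot(all(diff(tab$z_m) > 0), all(tab$rho_kg_m3 > 0))
# spot checks against values the standard prints
stopifnot(abs(tab$rho_kg_m3[tab$z_m == 100e3] - 5.604e-7) == 0)
stopifnot(abs(tab$mfp_m[tab$z_m == 90e3] - 0.0237) < 2e-4)
stopifnot(abs(tab$mfp_m[tab$z_m == 0] - 6.63e-8) < 2e-10)
stopifnot(abs(tab$rho_kg_m3[tab$z_m == 80e3] - 1.846e-5) < 4e-7)

tab$z_m <- format(as.integer(tab$z_m), scientific = FALSE, trim = TRUE)
write.csv(tab, "inst/extdata/ussa1976.csv", row.names = FALSE, quote = FALSE)
cat("wrote", nrow(tab), "rows\n")
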