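#' Equilibrium solubility of O2 and Ar in seawater
#'
#' Garcia & Gordon (1992) combined fit for O2 and Hamme & Emerson (2004) for
#' Ar, both in umol/kg at 1 atm moist air, as functions of temperature and
#' salinity via the scaled temperature `Ts = ln((298.15 - t)/(273.15 + t))`.
#'
#' @param temperature in-situ temperature, degrees C (-2 to 40).
#' @param salinity practical salinity (0 to 42).
#' @return equilibrium concentration, umol/kg.
#' @export
#' @examples
#' o2_saturation(10, 34)
o2_saturation <- function(temperature, salinity) {
  check_ts(temperature, salinity)
  Ts <- log((298.15 - temperature) / (273.15 + temperature))
  A <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  B <- c(-7.01577e-3, -7.70028e-3, -1.13864e-2, -9.51519e-3)
  C0 <- -2.75915e-7
  lnC <- A[1] + A[2] * Ts + A[3] * Ts^2 + A[4] * Ts^3 + A[5] * Ts^4 + A[6] * Ts^5 +
    salinity * (B[1] + B[2] * Ts + B[3] * Ts^2 + B[4] * Ts^3) + C0 * salinity^2
  exp(lnC)
}

#' @rdname o2_saturation
#' @export
ar_saturation <- function(temperature, salinity) {
  check_ts(temperature, salinity)
  Ts <- log((298.15 - temperature) / (273.15 + temperature))
  A <- c(2.79150, 3.17609, 4.13116, 4.90379)
  B <- c(-6.96233e-3, -7.66670e-3, -1.16888e-2)
  lnC <- A[1] + A[2] * Ts + A[3] * Ts^2 + A[4] * Ts^3 +
    salinity * (B[1] + B[2] * Ts + B[3] * Ts^2)
  exp(lnC)
}

check_ts <- function(temperature, salinity) {
  if (any(temperature < -2 | temperature > 40))
    stop("temperature outside physical range (-2 to 40 C)")
  if (any(salinity < 0 | salinity > 42))
    stop("salinity outside physical range (0 to 42)")
  invisible(TRUE)
}

#' Schmidt number of O2 in seawater
#'
#' Wanninkhof (2014) 4th-order polynomial in temperature, salinity 35.
#'
#' @param temperature degrees C.
#' @return dimensionless Schmidt number.
#' @export
schmidt_o2 <- function(temperature) {
  t <- temperature
  1920.4 - 135.6 * t + 5.2122 * t^2 - 0.10939 * t^3 + 0.00093777 * t^4
}

#' Instantaneous gas transfer velocity from wind speed
#'
#' Quadratic wind-speed dependence `k660 = coef * u10^2` (cm/hr at Schmidt
#' number 660; Wanninkhof 2014 coefficient 0.251), scaled by
#' `(Sc/660)^-1/2` and converted to m/day.
#'
#' @param u10 10-m wind speed, m/s (>= 0). Vectorised.
#' @param temperature surface temperature, degrees C (sets the Schmidt
#'   number).
#' @param coef quadratic coefficient, cm/hr per (m/s)^2.
#' @return gas transfer velocity for O2, m/day.
#' @export
gas_transfer_k <- function(u10, temperature, coef = 0.251) {
  if (any(u10 < 0)) stop("wind speeds must be non-negative")
  k660_cm_hr <- coef * u10^2
  k_cm_hr <- k660_cm_hr * (schmidt_o2(temperature) / 660)^(-0.5)
  k_cm_hr * 24 / 100
}

#' Mixed-layer-ventilation-weighted gas transfer velocity
#'
#' The gas transfer velocity relevant to an O2/Ar budget integrates over the
#' residence time of the mixed layer, so winds over a prior window (default
#' 60 days) are weighted by how much of the mixed layer each interval
#' ventilated that has not been re-ventilated since: with
#' `f_i = min(k_i * dt_i / mld, 1)`, interval `i` (counting back in time)
#' carries weight `f_i * prod_j(1 - f_j)` over all more recent intervals `j`,
#' normalized to sum to 1.
#'
#' @param time observation times of the wind series, days (any origin,
#'   increasing). Gaps > 1 day draw a warning.
#' @param u10 10-m wind speeds at `time`, m/s.
#' @param temperature surface temperature, degrees C.
#' @param mld mixed-layer depth, m (> 0).
#' @param window length of the prior interval to use, days.
#' @return list with `k` (weighted velocity, m/day), `weights`, `k_i`,
#'   `time_used`.
#' @export
weighted_gas_transfer <- function(time, u10, temperature, mld, window = 60) {
  stopifnot(length(time) == length(u10), mld > 0)
  if (length(time) == 0) stop("empty wind series")
  o <- order(time)
  time <- time[o]; u10 <- u10[o]
  if (diff(range(time)) < window)
    stop("wind series must span the ", window, "-day window")
  keep <- time >= max(time) - window
  time <- time[keep]; u10 <- u10[keep]
  if (length(time) > 1 && any(diff(time) > 1))
    warning("gap > 1 day in wind series", call. = FALSE)
  k_i <- gas_transfer_k(u10, temperature)
  dt <- diff(time)
  dt <- c(dt, if (length(dt)) stats::median(dt) else 1)  # last interval
  f <- pmin(k_i * dt / mld, 1)
  # most recent first for the survival product
  ord <- rev(seq_along(f))
  f_rev <- f[ord]
  surv <- c(1, cumprod(1 - f_rev))[seq_along(f_rev)]
  w_rev <- f_rev * surv
  w <- w_rev[order(ord)]
  if (sum(w) == 0) w <- rep(1 / length(w), length(w)) else w <- w / sum(w)
  list(k = sum(w * k_i), weights = w, k_i = k_i, time_used = time)
}

#' Biological O2/Ar supersaturation
#'
#' `Delta(O2/Ar) = (O2/Ar)_measured / (O2/Ar)_equilibrium(T,S) - 1`, the
#' biologically produced oxygen excess with physical (solubility, bubble)
#' effects removed by the Ar normalization.
#'
#' @param o2ar_meas measured O2/Ar ratio (dimensionless, > 0).
#' @param temperature,salinity surface values setting the equilibrium ratio.
#' @return Delta(O2/Ar), dimensionless.
#' @export
bio_supersaturation <- function(o2ar_meas, temperature, salinity) {
  if (any(o2ar_meas <= 0)) stop("measured O2/Ar must be positive")
  eq <- o2_saturation(temperature, salinity) / ar_saturation(temperature, salinity)
  o2ar_meas / eq - 1
}

#' Net community production from an O2/Ar mixed-layer budget
#'
#' At steady state with negligible subsurface mixing, the biological O2 flux
#' out of the mixed layer equals the air-sea flux of the biological O2
#' excess: `NCP_O2 = k * [O2]_sat * Delta(O2/Ar)` (mmol O2 m-2 d-1), divided
#' by the photosynthetic quotient (O2:C = 1.4) for carbon units. Negative
#' `Delta` yields negative NCP (net heterotrophy), which is returned as-is
#' and flagged.
#'
#' @param o2ar_meas measured O2/Ar ratio.
#' @param temperature,salinity surface values.
#' @param k gas transfer velocity, m/day (e.g. from
#'   [weighted_gas_transfer()]).
#' @param mld mixed-layer depth, m (for the volumetric rate).
#' @param o2c_ratio photosynthetic quotient, mol O2 per mol C.
#' @param density seawater density, kg/m3 (converts umol/kg to mmol/m3).
#' @return list with `areal` (mmol C m-2 d-1), `volumetric`
#'   (mmol C m-3 d-1), `annual` (mol C m-2 yr-1), `delta_o2ar`,
#'   `heterotrophic` flag.
#' @export
#' @examples
#' eq <- o2_saturation(12, 33) / ar_saturation(12, 33)
#' ncp(1.02 * eq, temperature = 12, salinity = 33, k = 3, mld = 30)
ncp <- function(o2ar_meas, temperature, salinity, k, mld,
                o2c_ratio = cr_constants()$o2c_ratio,
                density = cr_constants()$density_sw) {
  stopifnot(k >= 0, mld > 0)
  delta <- bio_supersaturation(o2ar_meas, temperature, salinity)
  o2sat_mmol_m3 <- o2_saturation(temperature, salinity) * density / 1000
  areal <- k * o2sat_mmol_m3 * delta / o2c_ratio
  list(areal = areal, volumetric = areal / mld,
       annual = areal * 365.25 / 1000,
       delta_o2ar = delta, heterotrophic = delta < 0)
}
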