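#' Configuration for the synthetic-ocean generator
#'
#' Defines the study conditions the generator emulates: six North Pacific
#' stations spanning subarctic to subtropical productivity regimes, a fixed
#' upper-ocean depth grid, a quasi-conservative background
#' \eqn{[Cr(VI)+Cr(III)_{NR}]} pool with NCP-scaled export drawdown above the
#' winter mixed layer, an NCP-proportional reactive Cr(III) maximum at the
#' surface, delta-53Cr generated from the exact two-pool isotope mass balance
#' with a constant Cr(III) offset, diel replicate sets with one-sided high
#' contamination, and the analytical noise of the measurements.
#'
#' @param n_stations number of stations.
#' @param lat station latitudes, degrees N.
#' @param ancp annual net community productivity per station,
#'   mol C m-2 yr-1 (defaults span 0.29-3.79, high to low latitude).
#' @param obs_ml on-station mixed-layer depths, m.
#' @param euphotic euphotic (1% isolume) depths, m.
#' @param winter_ml winter mixed-layer depth, m (integration reference).
#' @param depths sampling depth grid, m.
#' @param diel_depths depths with diel replicate sampling, m.
#' @param n_diel_range replicate count range per diel depth.
#' @param cr6nr_deep background pool below the winter mixed layer, nmol/kg.
#' @param delta_vi_nr delta-53Cr of the background pool, permil.
#' @param delta_cap true Delta-53Cr offset of the Cr(III) pool, permil.
#' @param epsilon_true enrichment factor for the Rayleigh-mode generator,
#'   permil (negative).
#' @param cr3_base baseline reactive Cr(III), nmol/kg.
#' @param cr3_ncp_slope Cr(III) added per unit volumetric NCP,
#'   nmol/kg per (mmol C m-3 d-1).
#' @param cr3_atten e-folding of the NCP-driven Cr(III) term in units of the
#'   euphotic depth.
#' @param crc_export imposed export Cr:C ratio, umol Cr per mol C (0 turns
#'   drawdown off and makes the background pool exactly constant).
#' @param drawdown_years effective accumulation time of the export deficit,
#'   years: upper waters above the permanent halocline exchange slowly, so the
#'   standing deficit integrates removal over several seasons. The default of
#'   5 puts surface deficits in the observed 0-0.3 nmol/kg range for the
#'   configured ANCP span.
#' @param n_d53_rep delta-53Cr replicate analyses averaged per bottle.
#' @param contamination_rate fraction of diel replicates contaminated high.
#' @param contamination_factor range of multiplicative contamination.
#' @param cr_rsd,d53_2sd,cr3_rel measurement noise: relative 1 SD on [Cr],
#'   permil 2 SD on delta-53Cr, relative 1 SD on [Cr(III)].
#' @return list of class `"cr_sim_config"`.
#' @export
cr_sim_config <- function(n_stations = 6,
                          lat = c(55, 50, 46, 42, 34, 24),
                          ancp = c(3.02, 2.22, 3.79, 1.57, 0.59, 0.29),
                          obs_ml = c(19.2, 33.8, 41.5, 28.7, 26.9, 39.7),
                          euphotic = c(40, 50, 60, 75, 100, 110),
                          winter_ml = 100,
                          depths = c(10, 25, 50, 75, 100, 150, 200),
                          diel_depths = c(10, 75),
                          n_diel_range = c(5, 21),
                          cr6nr_deep = 2.9,
                          delta_vi_nr = 1.178,
                          delta_cap = -1.08,
                          epsilon_true = -0.82,
                          cr3_base = 0.15,
                          cr3_ncp_slope = 1.5,
                          cr3_atten = 1.5,
                          crc_export = 2.0,
                          drawdown_years = 5,
                          n_d53_rep = 2,
                          contamination_rate = 0.10,
                          contamination_factor = c(1.8, 2.6),
                          cr_rsd = 0.0082, d53_2sd = 0.033, cr3_rel = 0.10) {
  stopifnot(n_stations >= 1,
            length(lat) >= n_stations, length(ancp) >= n_stations,
            length(obs_ml) >= n_stations, length(euphotic) >= n_stations,
            contamination_rate >= 0, contamination_rate < 0.5,
            epsilon_true < 0, cr6nr_deep > 0, crc_export >= 0)
  cfg <- as.list(environment())
  for (f in c("lat", "ancp", "obs_ml", "euphotic"))
    cfg[[f]] <- cfg[[f]][seq_len(n_stations)]
  structure(cfg, class = "cr_sim_config")
}

# volumetric NCP analogue over the euphotic layer, mmol C m-3 d-1
ncp_vol_from_ancp <- function(ancp, euphotic) ancp * 1000 / 365.25 / euphotic

# noise-free truth profiles for one station
station_truth <- function(cfg, i) {
  z <- cfg$depths
  ncp_vol <- ncp_vol_from_ancp(cfg$ancp[i], cfg$euphotic[i])
  cr3 <- cfg$cr3_base +
    cfg$cr3_ncp_slope * ncp_vol * exp(-cfg$cr3_atten * z / cfg$euphotic[i])
  # export drawdown of the background pool, uniform over the winter ML
  drawdown_nmolkg <- cfg$ancp[i] * cfg$crc_export * cfg$drawdown_years * 1e-6 /
    (cfg$winter_ml * cr_constants()$density_sw) * 1e9
  c_pool <- ifelse(z <= cfg$winter_ml, cfg$cr6nr_deep - drawdown_nmolkg,
                   cfg$cr6nr_deep)
  cr_total <- c_pool + cr3
  # delta-53Cr lies exactly on the constant-background mass-balance line;
  # the per-sample Cr(III) composition then follows from the exact Eq-3
  # balance with the actual (slightly drawn-down) background pool
  d53 <- cfg$delta_vi_nr + cfg$delta_cap * cr3 / cfg$cr6nr_deep
  list(depth = z, cr3 = cr3, cr6nr = c_pool, cr_total = cr_total, d53 = d53,
       ncp_vol = ncp_vol, drawdown = drawdown_nmolkg,
       delta_iii = delta_iii_mass_balance(d53, cr_total, cr3, cfg$delta_vi_nr))
}

#' Generate one synthetic station
#'
#' Produces a station-table `data.frame` (one profile row per depth carrying
#' noisy `[Cr]` and delta-53Cr, plus diel replicate rows carrying noisy
#' `[Cr(III)]`), the station context, and the latent truth. Contaminated
#' replicates are drawn one-sided high (roughly doubled), emulating
#' incomplete supernatant removal during shipboard coprecipitation.
#'
#' @param cfg a [cr_sim_config()].
#' @param i station index.
#' @param noise logical; `FALSE` returns exact noise-free values (and no
#'   contamination).
#' @return list with `samples`, `context`, `truth`. Randomness is drawn from
#'   the current RNG stream; seed via [simulate_ocean()] or `set.seed()`.
#' @export
simulate_station <- function(cfg = cr_sim_config(), i = 1, noise = TRUE) {
  tr <- station_truth(cfg, i)
  st <- paste0("st", i)
  nz <- length(tr$depth)
  s_d53 <- if (noise) cfg$d53_2sd / 2 else 0
  # delta values are means of replicate analyses (weighted-mean convention)
  nrep_d <- max(1L, cfg$n_d53_rep)
  d53_meas <- tr$d53 + stats::rnorm(nz, 0, s_d53 / sqrt(nrep_d))
  prof <- data.frame(
    station = st, lat = cfg$lat[i], depth_m = tr$depth,
    time_local = NA_character_,
    cr_total_nmolkg = pmax(tr$cr_total * (1 + if (noise)
      stats::rnorm(nz, 0, cfg$cr_rsd) else 0), 0),
    cr_total_sd = tr$cr_total * cfg$cr_rsd,
    d53cr_permil = d53_meas,
    d53cr_2se = cfg$d53_2sd / sqrt(nrep_d),
    cr3_nmolkg = NA_real_, cr3_sd = NA_real_,
    replicate = NA_integer_, day = NA_integer_,
    stringsAsFactors = FALSE
  )
  diel <- list()
  for (zd in intersect(cfg$diel_depths, tr$depth)) {
    nrep <- if (noise)
      sample(seq(cfg$n_diel_range[1], cfg$n_diel_range[2]), 1) else 8
    truth_cr3 <- tr$cr3[tr$depth == zd]
    vals <- truth_cr3 * (1 + if (noise) stats::rnorm(nrep, 0, cfg$cr3_rel) else 0)
    if (noise && cfg$contamination_rate > 0) {
      hit <- stats::runif(nrep) < cfg$contamination_rate
      vals[hit] <- vals[hit] * stats::runif(sum(hit), cfg$contamination_factor[1],
                                            cfg$contamination_factor[2])
    }
    times <- seq(0, by = 6, length.out = nrep)  # every 6 h across diel cycles
    diel[[length(diel) + 1]] <- data.frame(
      station = st, lat = cfg$lat[i], depth_m = zd,
      time_local = sprintf("%02d:00", times %% 24),
      cr_total_nmolkg = NA_real_, cr_total_sd = NA_real_,
      d53cr_permil = NA_real_, d53cr_2se = NA_real_,
      cr3_nmolkg = pmax(vals, 0), cr3_sd = truth_cr3 * cfg$cr3_rel,
      replicate = seq_len(nrep), day = times %/% 24 + 1,
      stringsAsFactors = FALSE)
  }
  # single (non-replicated) Cr(III) at the remaining depths, 10% noise
  single <- setdiff(tr$depth, cfg$diel_depths)
  prof$cr3_nmolkg[match(single, prof$depth_m)] <-
    pmax(tr$cr3[match(single, tr$depth)] *
           (1 + if (noise) stats::rnorm(length(single), 0, cfg$cr3_rel) else 0), 0)
  prof$cr3_sd[match(single, prof$depth_m)] <-
    tr$cr3[match(single, tr$depth)] * cfg$cr3_rel

  samples <- rbind(prof, do.call(rbind, diel))
  context <- data.frame(
    station = st, lat = cfg$lat[i],
    winter_ml_depth_m = cfg$winter_ml,
    obs_ml_depth_m = cfg$obs_ml[i],
    euphotic_depth_m = cfg$euphotic[i],
    ncp_vol_mmolc_m3_d = tr$ncp_vol,
    ancp_molc_m2_yr = cfg$ancp[i],
    stringsAsFactors = FALSE)
  list(samples = samples, context = context, truth = tr)
}

#' Generate a full synthetic survey
#'
#' Runs [simulate_station()] for every configured station under a single
#' seeded RNG stream; the same seed reproduces identical tables.
#'
#' @param cfg a [cr_sim_config()].
#' @param seed integer seed (`NULL` uses the current RNG state).
#' @param noise passed to [simulate_station()].
#' @return list with `samples` (all stations), `contexts`, `truth` (per
#'   station), `seed`.
#' @export
#' @examples
#' ocean <- simulate_ocean(seed = 1)
#' head(ocean$samples)
simulate_ocean <- function(cfg = cr_sim_config(), seed = NULL, noise = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  stations <- lapply(seq_len(cfg$n_stations), function(i)
    simulate_station(cfg, i, noise = noise))
  list(samples = do.call(rbind, lapply(stations, `[[`, "samples")),
       contexts = do.call(rbind, lapply(stations, `[[`, "context")),
       truth = lapply(stations, `[[`, "truth"),
       seed = seed)
}

#' Generate a Rayleigh-law global compilation analogue
#'
#' Emulates the global delta-53Cr vs ln[Cr] dataset: samples at remaining
#' fractions `f` of an initial reservoir follow `cr = f * cr0`,
#' `d53 = d0 + epsilon * ln(f)`, with relative noise on `[Cr]` and additive
#' noise on delta-53Cr.
#'
#' @param n number of samples.
#' @param cr0,d0 initial reservoir concentration (nmol/kg) and composition
#'   (permil).
#' @param epsilon true enrichment factor, permil.
#' @param f_range range of remaining fractions.
#' @param d53_2sd delta noise, permil 2 SD; `cr_rel_sd` relative 1 SD on [Cr].
#' @param cr_rel_sd relative noise on concentrations.
#' @param seed optional integer seed.
#' @return `data.frame` with `f`, `cr`, `d53` plus noise-free `cr_true`,
#'   `d53_true`.
#' @export
simulate_rayleigh <- function(n = 100, cr0 = 6, d0 = 0.45, epsilon = -0.82,
                              f_range = c(1 / 3, 1), d53_2sd = 0.033,
                              cr_rel_sd = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f <- stats::runif(n, f_range[1], f_range[2])
  exact <- rayleigh_predict(cr0, d0, epsilon, f)
  data.frame(f = f,
             cr = exact$cr * (1 + stats::rnorm(n, 0, cr_rel_sd)),
             d53 = exact$d53 + stats::rnorm(n, 0, d53_2sd / 2),
             cr_true = exact$cr, d53_true = exact$d53)
}

#' Generate synthetic double-spiked beam cycles
#'
#' Forward-models a spiked analysis: mixture abundances at the configured
#' `lambda` and true delta-53Cr, instrumental fractionation `beta` drawn per
#' analysis, per-cycle shot-noise-like beam noise (relative sigma
#' `1/sqrt(I * counts_per_unit)`), and optional Fe injected at the 56 monitor
#' (with its 54Fe isobar added to the 54 beam).
#'
#' @param true_d53 true sample delta-53Cr, permil.
#' @param lambda molar spike fraction.
#' @param beta instrumental fractionation exponent.
#' @param n_cycles measurement cycles.
#' @param i52 52Cr beam intensity (arbitrary units, e.g. V).
#' @param counts_per_unit equivalent ion counts per intensity unit per cycle;
#'   sets the noise floor. The default reproduces an internal precision
#'   (2 SEM over cycles) of roughly 0.02-0.03 permil.
#' @param fe56 Fe intensity at mass 56 (same units as `i52`), 0 for none.
#' @param system a [cr_isotope_system()].
#' @param seed optional integer seed.
#' @return `data.frame` of beam intensities, one row per cycle, columns
#'   `cycle`, `I49`, `I50`, `I51`, `I52`, `I53`, `I54`, `I56`.
#' @export
simulate_beams <- function(true_d53 = 0, lambda = 0.5, beta = 1.5,
                           n_cycles = 40, i52 = 10,
                           counts_per_unit = 2.6e8, fe56 = 0,
                           system = cr_isotope_system(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_cycles >= 1, i52 > 0, fe56 >= 0)
  ratios <- spike_forward(lambda, alpha_from_delta(true_d53, system), beta, system)
  clean <- c(I49 = 0, I50 = unname(ratios["r50"]) * i52, I51 = 0, I52 = i52,
             I53 = unname(ratios["r53"]) * i52,
             I54 = unname(ratios["r54"]) * i52 +
               fe56 * system$interference[["fe54_56"]],
             I56 = fe56)
  out <- t(vapply(seq_len(n_cycles), function(cy) {
    noisy <- clean
    pos <- clean > 0
    noisy[pos] <- clean[pos] +
      stats::rnorm(sum(pos), 0, sqrt(clean[pos] / counts_per_unit))
    noisy
  }, clean))
  data.frame(cycle = seq_len(n_cycles), out, check.names = FALSE)
}

#' Reduce a beam table to a single delta-53Cr and spike fraction
#'
#' Applies [interference_correct()] and [double_spike_invert()] per cycle and
#' aggregates: mean delta-53Cr, internal 2 SEM over cycles, mean lambda.
#'
#' @param beams output of [simulate_beams()] (or any table with the same
#'   columns).
#' @param system a [cr_isotope_system()].
#' @return list with `d53cr`, `d53cr_2sem`, `lambda`, `beta`, `n_cycles`.
#' @export
reduce_beams <- function(beams, system = cr_isotope_system()) {
  res <- lapply(seq_len(nrow(beams)), function(r) {
    corr <- interference_correct(beams[r, ], system)
    m <- c(r50 = unname(corr$cr[["I50"]] / corr$cr[["I52"]]),
           r53 = unname(corr$cr[["I53"]] / corr$cr[["I52"]]),
           r54 = unname(corr$cr[["I54"]] / corr$cr[["I52"]]))
    double_spike_invert(m, system)
  })
  d <- vapply(res, `[[`, numeric(1), "d53cr")
  list(d53cr = mean(d),
       d53cr_2sem = 2 * stats::sd(d) / sqrt(length(d)),
       lambda = mean(vapply(res, `[[`, numeric(1), "lambda")),
       beta = mean(vapply(res, `[[`, numeric(1), "beta")),
       n_cycles = length(d))
}

#' Generate a synthetic wind-speed series
#'
#' AR(1) 10-m wind speeds at 6-hourly resolution, floored at zero, for the
#' gas-exchange weighting.
#'
#' @param days series length, days.
#' @param dt_days time step, days.
#' @param mean_u10 long-term mean wind speed, m/s.
#' @param sd_u10 marginal SD, m/s; `ar1` lag-one autocorrelation per step.
#' @param ar1 AR(1) coefficient.
#' @param seed optional integer seed.
#' @return `data.frame` with `time_days`, `u10_ms`.
#' @export
simulate_winds <- function(days = 70, dt_days = 0.25, mean_u10 = 8,
                           sd_u10 = 3, ar1 = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(days / dt_days) + 1
  innov_sd <- sd_u10 * sqrt(1 - ar1^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd_u10)
  for (t in 2:n) x[t] <- ar1 * x[t - 1] + stats::rnorm(1, 0, innov_sd)
  data.frame(time_days = seq(0, by = dt_days, length.out = n),
             u10_ms = pmax(mean_u10 + x, 0))
}
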