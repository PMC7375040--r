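#' Chromium isotope system definition
#'
#' Bundles the constants the double-spike reduction needs: Cr isotope masses,
#' the NIST SRM 979 reference ratios (certificate values), a 50Cr-54Cr double
#' spike composition, and natural-abundance ratios used to strip isobaric
#' interferences of Ti, V and Fe from the Cr masses. The spike composition is
#' a synthetic stand-in with the right character (dominated by masses 50 and
#' 54): the actual spike stoichiometry used in any given lab is a calibration
#' input, so pass your own `spike_ratios` for real data.
#'
#' @param reference_ratios named numeric: SRM 979 `r50`, `r53`, `r54`
#'   (ratios to 52Cr).
#' @param spike_ratios named numeric: double-spike ratios to 52Cr.
#' @param masses atomic masses of 50,52,53,54Cr, amu.
#' @param interference natural-abundance monitor ratios: `ti50_49`, `v50_51`,
#'   `fe54_56`.
#' @return list of class `"cr_isotope_system"`.
#' @export
cr_isotope_system <- function(
    reference_ratios = c(r50 = 0.051859, r53 = 0.113387, r54 = 0.028222),
    spike_ratios     = c(r50 = 9.0,      r53 = 0.20,     r54 = 9.8),
    masses = c(m50 = 49.9460442, m52 = 51.9405062,
               m53 = 52.9406481, m54 = 53.9388792),
    interference = c(ti50_49 = 5.18 / 5.41, v50_51 = 0.250 / 99.750,
                     fe54_56 = 5.845 / 91.754)) {
  stopifnot(all(reference_ratios > 0), all(spike_ratios > 0),
            all(masses > 0), all(interference > 0))
  if (!(spike_ratios["r50"] > 1 && spike_ratios["r54"] > 1))
    warning("spike does not look 50/54-dominated", call. = FALSE)
  structure(list(reference_ratios = reference_ratios,
                 spike_ratios = spike_ratios,
                 masses = masses, interference = interference,
                 # log mass ratios to 52 for isotopes 50, 53, 54
                 logm = log(masses[c("m50", "m53", "m54")] / masses["m52"])),
            class = "cr_isotope_system")
}

#' Strip isobaric interferences from Cr beam intensities
#'
#' Ti, V and Fe interfere at Cr masses 50 (50Ti, 50V) and 54 (54Fe). Their
#' contributions are estimated from the interference-free monitor masses 49
#' (Ti), 51 (V) and 56 (Fe), scaled by natural abundance ratios, and
#' subtracted. A corrected beam more negative than `-3 * noise_sd` signals
#' contamination beyond what the monitors explain and is an error; small
#' negative excursions clip to zero with a flag.
#'
#' @param beams named numeric vector (or one-row data.frame) with `I49`,
#'   `I50`, `I51`, `I52`, `I53`, `I54`, `I56` (any units, e.g. V).
#' @param system a [cr_isotope_system()].
#' @param noise_sd 1-sigma beam noise used for the contamination check.
#' @return list with `cr` (named intensities at 50, 52, 53, 54) and
#'   `clipped` (logical).
#' @export
interference_correct <- function(beams, system = cr_isotope_system(),
                                 noise_sd = 0) {
  b <- unlist(beams)
  need <- c("I49", "I50", "I51", "I52", "I53", "I54", "I56")
  if (!all(need %in% names(b))) stop("beams must contain ", paste(need, collapse = ", "))
  if (any(b[c("I49", "I51", "I56")] < 0)) stop("monitor intensities must be >= 0")
  itf <- system$interference
  cr50 <- b[["I50"]] - b[["I49"]] * itf[["ti50_49"]] - b[["I51"]] * itf[["v50_51"]]
  cr54 <- b[["I54"]] - b[["I56"]] * itf[["fe54_56"]]
  corrected <- c(I50 = cr50, I52 = b[["I52"]], I53 = b[["I53"]], I54 = cr54)
  if (any(corrected < -3 * noise_sd - 1e-15))
    stop("corrected beam below -3 sigma of noise: unexplained contamination")
  clipped <- corrected < 0
  corrected[clipped] <- 0
  list(cr = corrected, clipped = any(clipped))
}

# sample isotope abundances (50,52,53,54) fractionated from the reference by
# exponential-law exponent `alpha`, plus d/dalpha
sample_abundances <- function(alpha, system) {
  P <- c(system$logm[1], 0, system$logm[2], system$logm[3])
  r <- c(system$reference_ratios[["r50"]], 1,
         system$reference_ratios[["r53"]], system$reference_ratios[["r54"]]) *
    exp(alpha * P)
  S <- sum(r)
  dr <- r * P
  list(a = r / S, da = (dr * S - r * sum(dr)) / S^2)
}

spike_abundances <- function(system) {
  r <- c(system$spike_ratios[["r50"]], 1,
         system$spike_ratios[["r53"]], system$spike_ratios[["r54"]])
  r / sum(r)
}

#' Forward double-spike mixing model
#'
#' Mixes a molar fraction `lambda` of spike with `1 - lambda` of sample
#' (reference composition fractionated by natural exponent `alpha` under the
#' exponential law), applies instrumental fractionation `beta`, and returns
#' the three measured ratios to 52Cr. The exact inverse of
#' [double_spike_invert()].
#'
#' @param lambda molar spike fraction of total Cr, in (0, 1).
#' @param alpha natural fractionation exponent (use [alpha_from_delta()] to
#'   set a target delta-53Cr).
#' @param beta instrumental fractionation exponent.
#' @param system a [cr_isotope_system()].
#' @return named numeric `r50`, `r53`, `r54`.
#' @export
spike_forward <- function(lambda, alpha, beta, system = cr_isotope_system()) {
  stopifnot(lambda > 0, lambda < 1)
  a_sam <- sample_abundances(alpha, system)$a
  x <- lambda * spike_abundances(system) + (1 - lambda) * a_sam
  P <- c(system$logm[1], system$logm[2], system$logm[3])
  m <- (x[c(1, 3, 4)] / x[2]) * exp(beta * P)
  stats::setNames(m, c("r50", "r53", "r54"))
}

#' Convert between delta-53Cr and the exponential-law exponent
#'
#' Under the exponential law the sample 53/52 ratio is the reference ratio
#' times `(m53/m52)^alpha`, so `delta = 1000 * ((m53/m52)^alpha - 1)`.
#'
#' @param delta delta-53Cr, permil.
#' @param system a [cr_isotope_system()].
#' @return the exponent `alpha` (for `alpha_from_delta`) or delta, permil
#'   (for `delta_from_alpha`).
#' @export
alpha_from_delta <- function(delta, system = cr_isotope_system()) {
  log1p(delta / 1000) / system$logm[["m53"]]
}

#' @rdname alpha_from_delta
#' @param alpha exponential-law exponent.
#' @export
delta_from_alpha <- function(alpha, system = cr_isotope_system()) {
  1000 * expm1(alpha * system$logm[["m53"]])
}

#' Invert a double-spiked Cr measurement
#'
#' Newton-Raphson solution of the three-equation double-spike system: the
#' measured 50/52, 53/52 and 54/52 ratios equal a molar mixture (fraction
#' `lambda` spike) of the spike and a sample whose composition is the
#' reference fractionated by natural exponent `alpha`, with the whole mixture
#' fractionated instrumentally by exponent `beta` (exponential law on both).
#' Uses an analytic Jacobian; converges quadratically from the default start
#' (0.5, 0, 0) across the feasible region.
#'
#' @param measured named numeric `r50`, `r53`, `r54`: interference-corrected
#'   ratios to 52Cr. Intensity scaling cancels (ratios only).
#' @param system a [cr_isotope_system()].
#' @param start initial `(lambda, alpha, beta)`.
#' @param tol convergence tolerance on the residual norm.
#' @param maxit maximum Newton iterations.
#' @return list of class `"cr_inversion"`: `lambda`, `alpha`, `beta`,
#'   `d53cr` (permil vs the reference), `converged`, `iterations`,
#'   `residual_norm`.
#' @export
#' @examples
#' sys <- cr_isotope_system()
#' m <- spike_forward(0.45, alpha_from_delta(1.0), 1.5, sys)
#' double_spike_invert(m, sys)$d53cr   # ~1.000
double_spike_invert <- function(measured, system = cr_isotope_system(),
                                start = c(lambda = 0.5, alpha = 0, beta = 0),
                                tol = 1e-12, maxit = 100) {
  meas <- unlist(measured)[c("r50", "r53", "r54")]
  if (anyNA(meas) || any(meas <= 0)) stop("measured ratios must be positive")
  a_sp <- spike_abundances(system)
  P3 <- c(system$logm[1], system$logm[2], system$logm[3])  # 50, 53, 54
  theta <- start
  converged <- FALSE
  for (it in seq_len(maxit)) {
    lam <- theta[1]; alf <- theta[2]; bet <- theta[3]
    sa <- sample_abundances(alf, system)
    x <- lam * a_sp + (1 - lam) * sa$a
    e_b <- exp(bet * P3)
    idx <- c(1, 3, 4)
    M <- (x[idx] / x[2]) * e_b
    FF <- M - meas
    if (sqrt(sum(FF^2)) < tol) { converged <- TRUE; break }
    dx_dlam <- a_sp - sa$a
    dx_dalf <- (1 - lam) * sa$da
    dratio <- function(dx) (dx[idx] * x[2] - x[idx] * dx[2]) / x[2]^2 * e_b
    J <- cbind(dratio(dx_dlam), dratio(dx_dalf), M * P3)
    step <- solve(J, FF)
    # damp steps that would leave the feasible region in lambda
    lam_new <- lam - step[1]
    if (lam_new <= 0 || lam_new >= 1) step <- step * 0.5
    theta <- theta - step
  }
  if (!converged) {
    lam <- theta[1]; alf <- theta[2]; bet <- theta[3]
    sa <- sample_abundances(alf, system)
    x <- lam * a_sp + (1 - lam) * sa$a
    M <- (x[c(1, 3, 4)] / x[2]) * exp(bet * P3)
    if (sqrt(sum((M - meas)^2)) < tol) converged <- TRUE
  }
  if (theta[1] <= 0 || theta[1] >= 1)
    stop("inversion left the feasible region: lambda = ", signif(theta[1], 4))
  if (!converged)
    warning("double-spike inversion did not converge in ", maxit, " iterations",
            call. = FALSE)
  structure(list(lambda = unname(theta[1]), alpha = unname(theta[2]),
                 beta = unname(theta[3]),
                 d53cr = delta_from_alpha(unname(theta[2]), system),
                 converged = converged, iterations = it,
                 residual_norm = sqrt(sum(FF^2))),
            class = "cr_inversion")
}

#' @export
print.cr_inversion <- function(x, ...) {
  cat(sprintf("double-spike inversion: lambda = %.4f, d53Cr = %+.4f permil (alpha = %+.4f, beta = %+.4f)%s\n",
              x$lambda, x$d53cr, x$alpha, x$beta,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

# Analytic Jacobian of the forward residuals at (lambda, alpha, beta);
# exposed for numerical verification.
spike_jacobian <- function(lambda, alpha, beta, system = cr_isotope_system()) {
  a_sp <- spike_abundances(system)
  P3 <- c(system$logm[1], system$logm[2], system$logm[3])
  sa <- sample_abundances(alpha, system)
  x <- lambda * a_sp + (1 - lambda) * sa$a
  e_b <- exp(beta * P3)
  idx <- c(1, 3, 4)
  M <- (x[idx] / x[2]) * e_b
  dx_dlam <- a_sp - sa$a
  dx_dalf <- (1 - lambda) * sa$da
  dratio <- function(dx) (dx[idx] * x[2] - x[idx] * dx[2]) / x[2]^2 * e_b
  unname(cbind(dratio(dx_dlam), dratio(dx_dalf), M * P3))
}

#' Isotope dilution concentration from the spike fraction
#'
#' With `lambda` the molar fraction of spike Cr in the spike-sample mixture,
#' the sample contributes `spike_pmol * (1 - lambda) / lambda` pmol Cr.
#'
#' @param spike_pmol moles of spike Cr added, pmol (> 0).
#' @param lambda molar spike fraction from [double_spike_invert()] (in (0,1)).
#' @param sample_mass_kg processed seawater mass, kg (> 0).
#' @return concentration, nmol/kg.
#' @export
#' @examples
#' isotope_dilution_conc(50, 0.5, 0.030)  # 1.667 nmol/kg
isotope_dilution_conc <- function(spike_pmol, lambda, sample_mass_kg) {
  if (inherits(lambda, "cr_inversion")) lambda <- lambda$lambda
  if (any(spike_pmol <= 0)) stop("spike_pmol must be positive")
  if (any(sample_mass_kg <= 0)) stop("sample_mass_kg must be positive")
  if (any(lambda <= 0 | lambda >= 1)) stop("lambda must be in (0, 1)")
  spike_pmol * (1 - lambda) / lambda / sample_mass_kg / 1000
}

#' Normalize sample delta-53Cr to the daily standard mean
#'
#' Subtracts the daily mean delta-53Cr of bracketing double-spiked reference
#' standards from each sample value, and reports the 2 SEM of the standard
#' replicates as the session-level uncertainty.
#'
#' @param sample_d53 sample delta-53Cr value(s), permil.
#' @param bracketing_standards delta-53Cr of the day's standards, permil
#'   (>= 2 values).
#' @return list with `d53cr` (normalized values), `standard_mean`,
#'   `standard_2sem`, `n_standards`.
#' @export
daily_normalize <- function(sample_d53, bracketing_standards) {
  if (length(bracketing_standards) < 2) stop("need at least 2 standards")
  m <- mean(bracketing_standards)
  list(d53cr = sample_d53 - m, standard_mean = m,
       standard_2sem = 2 * stats::sd(bracketing_standards) /
         sqrt(length(bracketing_standards)),
       n_standards = length(bracketing_standards))
}

#' Fe monitor level producing a given uncorrected delta-53Cr bias
#'
#' Finds the 56Fe monitor intensity (relative to a unit 52Cr beam) whose
#' uncorrected 54Fe contribution shifts the reduced delta-53Cr by
#' `target_bias` permil. Used to calibrate interference-injection levels in
#' the beam generator against a stated bias budget.
#'
#' @param target_bias delta-53Cr shift, permil.
#' @param lambda,alpha,beta true mixture parameters at which the bias is
#'   evaluated.
#' @param system a [cr_isotope_system()].
#' @return 56Fe intensity per unit 52Cr intensity.
#' @export
fe_level_for_bias <- function(target_bias = 0.005, lambda = 0.5, alpha = 0,
                              beta = 1.5, system = cr_isotope_system()) {
  clean <- spike_forward(lambda, alpha, beta, system)
  d0 <- double_spike_invert(clean, system)$d53cr
  bias_at <- function(i56) {
    m <- clean
    m["r54"] <- m["r54"] + i56 * system$interference[["fe54_56"]]
    double_spike_invert(m, system)$d53cr - d0
  }
  # the bias magnitude grows monotonically with the Fe level; its sign is a
  # property of the spike geometry, so solve on the magnitude
  s <- sign(bias_at(1e-3))
  f <- function(i56) bias_at(i56) - s * abs(target_bias)
  hi <- 1e-4
  while (f(hi) * f(0) > 0 && hi < 10) hi <- hi * 10
  stats::uniroot(f, c(0, hi), tol = 1e-14)$root
}
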