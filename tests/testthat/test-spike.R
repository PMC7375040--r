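sys <- cr_isotope_system()

test_that("interference correction strips Ti, V and Fe exactly", {
  # zero monitors: identity on the Cr masses
  b <- c(I49 = 0, I50 = 0.5, I51 = 0, I52 = 10, I53 = 1.1, I54 = 0.3, I56 = 0)
  expect_equal(unname(interference_correct(b, sys)$cr),
               unname(b[c("I50", "I52", "I53", "I54")]))

  # forward oracle: inject known Ti, V, Fe and recover the pure Cr beams
  itf <- sys$interference
  ti49 <- 0.02; v51 <- 0.5; fe56 <- 0.04
  cr_true <- c(I50 = 0.52, I52 = 10, I53 = 1.13, I54 = 0.28)
  bm <- c(I49 = ti49,
          I50 = cr_true[["I50"]] + ti49 * itf[["ti50_49"]] + v51 * itf[["v50_51"]],
          I51 = v51, I52 = 10, I53 = 1.13,
          I54 = cr_true[["I54"]] + fe56 * itf[["fe54_56"]], I56 = fe56)
  expect_equal(unname(interference_correct(bm, sys)$cr), unname(cr_true),
               tolerance = 1e-14)

  # small negative excursions clip with a flag; gross deficits error
  neg <- c(I49 = 0, I50 = -1e-12, I51 = 0, I52 = 10, I53 = 1, I54 = 0.3, I56 = 0)
  expect_true(interference_correct(neg, sys, noise_sd = 1e-6)$clipped)
  bad <- c(I49 = 0, I50 = -0.5, I51 = 0, I52 = 10, I53 = 1, I54 = 0.3, I56 = 0)
  expect_error(interference_correct(bad, sys, noise_sd = 1e-6), "contamination")
})

test_that("unfractionated mixtures invert to the exact configuration", {
  m <- spike_forward(0.5, 0, 0, sys)
  inv <- double_spike_invert(m, sys)
  expect_true(inv$converged)
  expect_equal(inv$lambda, 0.5, tolerance = 1e-12)
  expect_equal(inv$alpha, 0, tolerance = 1e-12)
  expect_equal(inv$beta, 0, tolerance = 1e-12)
  expect_equal(inv$d53cr, 0, tolerance = 1e-10)
})

test_that("forward/invert round trip recovers delta-53Cr across the feasible region", {
  inv <- double_spike_invert(
    spike_forward(0.45, alpha_from_delta(1.0, sys), 1.5, sys), sys)
  expect_equal(inv$d53cr, 1.0, tolerance = 1e-6)
  expect_equal(inv$lambda, 0.45, tolerance = 1e-9)
  expect_equal(inv$beta, 1.5, tolerance = 1e-9)

  set.seed(31)
  worst <- 0
  for (r in 1:200) {
    lam <- runif(1, 0.2, 0.8); d <- runif(1, -2, 2); b <- runif(1, -2, 2)
    out <- double_spike_invert(
      spike_forward(lam, alpha_from_delta(d, sys), b, sys), sys)
    worst <- max(worst, abs(out$d53cr - d))
  }
  expect_lt(worst, 1e-6)
})

test_that("the analytic Jacobian matches central finite differences", {
  set.seed(32)
  for (r in 1:10) {
    lam <- runif(1, 0.2, 0.8); a <- runif(1, -0.5, 0.5); b <- runif(1, -2, 2)
    J <- crseawater:::spike_jacobian(lam, a, b, sys)
    Jfd <- fd_jacobian(lam, a, b, sys)
    expect_lt(max(abs(J - Jfd) / pmax(abs(Jfd), 1e-8)), 1e-5)
  }
})

test_that("inversion depends only on ratios, not beam intensity", {
  m <- spike_forward(0.6, alpha_from_delta(-0.5, sys), 0.8, sys)
  # scaling all intensities cancels in the ratios fed to the inversion
  beams <- c(I49 = 0, I50 = m[["r50"]], I51 = 0, I52 = 1,
             I53 = m[["r53"]], I54 = m[["r54"]], I56 = 0)
  for (scale in c(1, 7, 1e3)) {
    corr <- interference_correct(beams * scale, sys)
    mm <- c(r50 = unname(corr$cr[["I50"]] / corr$cr[["I52"]]),
            r53 = unname(corr$cr[["I53"]] / corr$cr[["I52"]]),
            r54 = unname(corr$cr[["I54"]] / corr$cr[["I52"]]))
    expect_equal(double_spike_invert(mm, sys)$d53cr, -0.5, tolerance = 1e-8)
  }
})

test_that("isotope dilution converts the spike fraction to concentration", {
  expect_equal(isotope_dilution_conc(50, 0.5, 0.030), 50 / 0.030 / 1000)
  expect_equal(isotope_dilution_conc(50, 0.5, 0.030), 1.667, tolerance = 1e-3)
  # lambda -> 1: all Cr is spike, sample concentration vanishes
  expect_lt(isotope_dilution_conc(50, 0.999999, 0.030), 1e-4)
  expect_error(isotope_dilution_conc(50, 1, 0.030), "lambda")
  expect_error(isotope_dilution_conc(-1, 0.5, 0.030), "positive")
})

test_that("daily standard normalization subtracts the session mean", {
  std <- c(0.012, 0.008, 0.010)
  out <- daily_normalize(0.950, std)
  expect_equal(out$d53cr, 0.940)
  expect_equal(out$standard_mean, 0.010)
  expect_equal(daily_normalize(0.5, c(0, 0, 0))$d53cr, 0.5)
  expect_error(daily_normalize(0.5, 0.01), "2 standards")
})

test_that("beam reduction reproduces concentrations within stated precision", {
  # lambda chosen by the spike addition; reduce noisy beams end-to-end
  set.seed(33)
  spike_pmol <- 50; mass_kg <- 0.030; conc_true <- 2.0  # nmol/kg
  sample_pmol <- conc_true * mass_kg * 1000
  lam_true <- spike_pmol / (spike_pmol + sample_pmol)
  b <- simulate_beams(true_d53 = 0.9, lambda = lam_true, beta = 1.2)
  red <- reduce_beams(b, sys)
  conc <- isotope_dilution_conc(spike_pmol, red$lambda, mass_kg)
  expect_equal(conc, conc_true, tolerance = 0.0082)
})
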