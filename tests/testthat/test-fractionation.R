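test_that("exact lines are recovered exactly, in both modes", {
  x <- c(0, 1, 2)
  f <- cr_fractionation(x, 2 * x + 1, mode = "cr3")
  expect_equal(coef(f), c(intercept = 1, slope = 2))
  expect_equal(f$r2, 1)

  # Rayleigh data: slope of delta on ln[Cr] is epsilon
  cr <- c(5, 4, 3, 2.5, 2)
  d <- 1.0 - 0.80 * log(cr / 5)
  g <- fit_global_epsilon(cr, d)
  expect_equal(g$epsilon, -0.80, tolerance = 1e-10)
  expect_equal(g$r2, 1)

  expect_error(cr_fractionation(c(1, 2), c(1, 2)), "3 points")
  expect_error(cr_fractionation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(cr_fractionation(c(-1, 2, 3), c(1, 2, 3), mode = "lncr"),
               "positive")
})

test_that("errors-in-variables fit agrees with OLS under uniform uncertainties", {
  set.seed(11)
  x <- runif(20, 0.05, 0.35)
  y <- 1.178 - 0.372 * x + rnorm(20, 0, 0.0165)
  ols <- cr_fractionation(x, y)
  yk <- cr_fractionation(x, y, sx = rep(1e-9, 20), sy = rep(0.0165, 20),
                         method = "york")
  expect_equal(yk$slope, ols$slope, tolerance = 1e-6)
  expect_equal(yk$intercept, ols$intercept, tolerance = 1e-6)
  expect_error(cr_fractionation(x, y, method = "york"), "requires sx and sy")
})

test_that("OLS confidence intervals achieve near-nominal coverage", {
  set.seed(12)
  hits_slope <- 0; hits_int <- 0
  n_rep <- 200
  for (r in 1:n_rep) {
    x <- runif(12, 0.05, 0.35)
    y <- 1.18 - 0.37 * x + rnorm(12, 0, 0.0165)
    f <- cr_fractionation(x, y)
    ci <- confint(f)
    hits_int <- hits_int + (ci[1, 1] <= 1.18 && 1.18 <= ci[1, 2])
    hits_slope <- hits_slope + (ci[2, 1] <= -0.37 && -0.37 <= ci[2, 2])
  }
  expect_gte(hits_slope / n_rep, 0.90)
  expect_gte(hits_int / n_rep, 0.90)
})

test_that("mass balance turns the fitted line into the Cr(III) offset", {
  # the published pair: intercept 1.178, slope -1.08/2.9
  x <- seq(0.05, 0.35, length.out = 6)
  f <- cr_fractionation(x, 1.178 + (-1.08 / 2.9) * x, cr6nr_const = 2.9)
  expect_equal(f$delta_vi_nr, 1.178, tolerance = 1e-9)
  expect_equal(f$delta_cap, -1.08, tolerance = 1e-9)

  # closed-form identity, any fit: delta_cap = slope * C exactly
  set.seed(13)
  for (r in 1:10) {
    y <- 1.2 + rnorm(6, 0, 0.05)
    fr <- cr_fractionation(x, y, cr6nr_const = 2.9)
    expect_identical(fr$delta_cap, fr$slope * 2.9)
  }

  # zero slope: no offset, Cr(III) isotopically identical to the total pool
  f0 <- cr_fractionation(x, rep(1.1, 6) + 1e-15 * x)
  mb0 <- mass_balance_delta_iii(list(slope = 0, intercept = 1.1, se_slope = 0,
                                     n = 6, vcov = matrix(0, 2, 2)), 2.9)
  expect_equal(mb0$delta_cap, 0)
  expect_equal(mb0$delta_iii_at(c(0.1, 0.3)), c(1.1, 1.1))

  # Monte-Carlo CI construction agrees with slope-CI scaling
  xs <- runif(12, 0.05, 0.35)
  fit <- cr_fractionation(xs, 1.178 - 0.372 * xs + rnorm(12, 0, 0.0165))
  set.seed(14)
  mc <- mass_balance_delta_iii(fit, 2.9, ci = "monte_carlo", nsim = 50000)
  sc <- mass_balance_delta_iii(fit, 2.9, ci = "slope_ci")
  expect_equal(mc$delta_cap_ci, sc$delta_cap_ci, tolerance = 0.05)
})

test_that("per-sample mass balance is conserved when delta_iii is back-computed", {
  oc <- simulate_ocean(seed = 21, noise = FALSE)
  for (tr in oc$truth) {
    d3 <- delta_iii_mass_balance(tr$d53, tr$cr_total, tr$cr3, 1.178)
    lhs <- tr$d53 * tr$cr_total
    rhs <- 1.178 * tr$cr6nr + d3 * tr$cr3
    expect_equal(lhs, rhs, tolerance = 1e-12)
    expect_equal(d3, tr$delta_iii, tolerance = 1e-12)
  }
})

test_that("the linear approximation to self-consistent mixing is accurate", {
  # solving the mixing relation for delta_total numerically and fitting a
  # line recovers the configured offset essentially exactly
  x <- seq(0.05, 0.35, length.out = 40)
  d <- implicit_mixing_delta(x, dvi = 1.2, dcap = -1.0, C = 2.9)
  f <- cr_fractionation(x, d, cr6nr_const = 2.9)
  expect_lte(abs(f$delta_cap - (-1.0)), 0.05)

  # with a fixed Cr(III)-pool composition the relation is genuinely
  # hyperbolic; the linear fit then understates the offset at x = 0 --
  # the quantified cost of the quasi-linearity assumption
  dh <- fixed_pool_mixing_delta(x, dvi = 1.2, d3 = 0.2, C = 2.9)
  fh <- cr_fractionation(x, dh, cr6nr_const = 2.9)
  expect_lt(abs(fh$delta_cap), 1.0)        # attenuated toward zero
  expect_lt(abs(fh$delta_cap - (-1.0)), 0.2)  # but within 20%
})

test_that("Rayleigh prediction composes and inverts the ln-linear fit", {
  expect_equal(rayleigh_predict(3, 0.9, -0.82, 1)$d53, 0.9)
  expect_equal(rayleigh_predict(3, 0.9, -0.82, 1)$cr, 3)
  r <- rayleigh_predict(3, 0.9, -0.82, 0.5)
  expect_equal(r$d53, 0.9 - 0.82 * log(0.5), tolerance = 1e-12)
  expect_equal(r$d53, 1.4684, tolerance = 1e-4)

  # semigroup: two partial removals equal one combined removal
  s1 <- rayleigh_predict(3, 0.9, -0.82, 0.8)
  s2 <- rayleigh_predict(s1$cr, s1$d53, -0.82, 0.7)
  s12 <- rayleigh_predict(3, 0.9, -0.82, 0.8 * 0.7)
  expect_equal(s2$cr, s12$cr)
  expect_equal(s2$d53, s12$d53)

  # mutual inverse with the fit on noise-free curves
  f <- seq(0.4, 1, length.out = 10)
  curve <- rayleigh_predict(6, 0.45, -0.82, f)
  fit <- fit_global_epsilon(curve$cr, curve$d53)
  expect_equal(fit$epsilon, -0.82, tolerance = 1e-10)
  expect_error(rayleigh_predict(3, 0.9, -0.82, 0), "\\(0, 1\\]")
})

test_that("model methods behave like a standard fitted model", {
  set.seed(15)
  x <- runif(10, 0.05, 0.35)
  y <- 1.18 - 0.37 * x + rnorm(10, 0, 0.01)
  f <- cr_fractionation(x, y)
  expect_output(print(f), "Delta53Cr")
  expect_named(coef(f), c("intercept", "slope"))
  expect_equal(unname(predict(f, newdata = 0.2)),
               f$intercept + f$slope * 0.2)
  expect_equal(length(residuals(f)), 10)
  expect_equal(fitted <- predict(f), y - residuals(f))
  s <- summary(f)
  expect_s3_class(s, "summary.cr_fracfit")
  # formula interface matches the default interface
  df <- data.frame(d53 = y, cr3 = x)
  ff <- cr_fractionation(d53 ~ cr3, data = df)
  expect_equal(coef(ff), coef(f))
  pdf(NULL); plot(f); dev.off()
})
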