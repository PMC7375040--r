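test_that("tau test flags a gross outlier and leaves clean sets alone", {
  expect_equal(modified_thompson_tau(c(0.10, 0.10, 0.10, 0.10)),
               rep(FALSE, 4))
  # hand-checked case: only the fourth value exceeds tau * sd
  expect_equal(modified_thompson_tau(c(0.10, 0.11, 0.09, 0.45)),
               c(FALSE, FALSE, FALSE, TRUE))
  # identical mask from the classic outward iteration on a single outlier
  expect_equal(modified_thompson_tau(c(0.10, 0.11, 0.09, 0.45),
                                     iteration = "outward", per_point = TRUE),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(modified_thompson_tau(c(0.1, 0.9)), c(FALSE, FALSE))
  expect_error(modified_thompson_tau(c(0.1, NA, 0.2)), "NA")
})

test_that("rejection is permutation-invariant, scale-equivariant and bounded", {
  set.seed(101)
  for (i in 1:30) {
    n <- sample(4:15, 1)
    x <- rnorm(n)
    if (i %% 2 == 0) x[1] <- x[1] + 6  # sometimes plant an outlier
    m <- modified_thompson_tau(x)
    p <- sample(n)
    expect_equal(modified_thompson_tau(x[p]), m[p])
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(modified_thompson_tau(a * x + b), m)
    expect_equal(modified_thompson_tau(-x), m)
    expect_lte(sum(m), ceiling(n / 2))
  }
})

test_that("clean Gaussian data is rarely rejected, contamination is caught", {
  set.seed(202)
  rej <- 0; tot <- 0
  for (g in 1:300) {
    m <- modified_thompson_tau(rnorm(10))
    rej <- rej + sum(m); tot <- tot + 10
  }
  expect_lte(rej / tot, 0.05)

  flagged <- 0; caught <- 0; ncont <- 0; tot <- 0
  for (g in 1:300) {
    n <- 15
    x <- 0.2 * (1 + rnorm(n, 0, 0.10))
    hit <- runif(n) < 0.10
    x[hit] <- x[hit] * runif(sum(hit), 1.8, 2.6)
    m <- modified_thompson_tau(x)
    flagged <- flagged + sum(m); caught <- caught + sum(m & hit)
    ncont <- ncont + sum(hit); tot <- tot + n
  }
  expect_gt(caught / ncont, 0.9)            # clustered outliers not masked
  expect_equal(flagged / tot, 0.10, tolerance = 0.3)
})

test_that("diel aggregation assigns means, SDs and replicate flags", {
  df <- data.frame(station = "a", depth_m = 10,
                   cr3_nmolkg = rep(0.2, 5))
  g <- aggregate_diel(df)
  expect_equal(g$mean, 0.2)
  expect_equal(g$sd, 0)
  expect_true(g$diel_replicated)

  # single value: conservative 10% relative uncertainty
  g1 <- aggregate_diel(data.frame(station = "a", depth_m = 10, cr3_nmolkg = 0.20))
  expect_equal(g1$sd, 0.020)
  expect_false(g1$diel_replicated)

  # outliers excluded from the mean
  dfo <- data.frame(station = "a", depth_m = 10,
                    cr3_nmolkg = c(0.20, 0.21, 0.19, 0.20, 0.48))
  go <- aggregate_diel(dfo)
  expect_equal(go$n_outliers, 1)
  expect_equal(go$mean, mean(c(0.20, 0.21, 0.19, 0.20)))

  expect_error(aggregate_diel(data.frame(station = "a", depth_m = 1,
                                         cr3_nmolkg = NA_real_)), "no non-missing")
})

test_that("aggregation recovers generator truth within its uncertainty", {
  set.seed(303)
  cfg <- cr_sim_config()
  st <- simulate_station(cfg, 1)
  truth <- st$truth
  g <- aggregate_diel(st$samples)
  for (r in seq_len(nrow(g))) {
    if (!g$diel_replicated[r]) next
    tr <- truth$cr3[truth$depth == g$depth_m[r]]
    expect_lt(abs(g$mean[r] - tr), 2 * max(g$sd[r], tr * cfg$cr3_rel))
  }
})

test_that("diel cycle detection finds injected signals and respects the null", {
  t <- seq(0, 48, by = 4)
  set.seed(404)
  # null: flat with noise
  flat <- detect_diel_cycle(t, rnorm(length(t), 0.2, 0.02))
  expect_false(flat$significant)
  # injected 0.2 amplitude on the same noise: detected, amplitude recovered
  y <- 0.2 + 0.2 * sin(2 * pi * t / 24 + 1) + rnorm(length(t), 0, 0.02)
  d <- detect_diel_cycle(t, y)
  expect_true(d$significant)
  expect_equal(d$amplitude, 0.2, tolerance = 0.15)
  # false-positive rate near the nominal level over many null series
  fp <- 0
  for (r in 1:200)
    fp <- fp + detect_diel_cycle(t, rnorm(length(t), 0.2, 0.02))$significant
  expect_lt(fp / 200, 0.10)
  expect_gt(fp / 200, 0.005)
  expect_error(detect_diel_cycle(c(0, 6, 12), c(1, 2, 3)), "4 time points")
  expect_error(detect_diel_cycle(c(0, 2, 4, 6), c(1, 2, 3, 4)), "24-h")
})
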