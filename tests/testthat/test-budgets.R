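test_that("trapezoid layer mean is exact on flat and linear profiles", {
  z <- c(0, 25, 50, 75, 100)
  expect_equal(trapezoid_layer_mean(z, rep(3, 5), 0, 100), 3)
  # c(z) = 2 + 0.01 z integrates to a mean of 2.5 over [0, 100]
  expect_equal(trapezoid_layer_mean(z, 2 + 0.01 * z, 0, 100), 2.5)
  # piecewise-linear exactness at arbitrary bounds and random knots
  set.seed(41)
  for (r in 1:10) {
    zz <- sort(c(0, runif(6, 0, 200), 200))  # knots covering the layer
    cc <- 3 - 0.002 * zz
    expect_equal(trapezoid_layer_mean(zz, cc, 20, 180),
                 3 - 0.002 * (20 + 180) / 2, tolerance = 1e-10)
  }
  expect_error(trapezoid_layer_mean(c(150, 160), c(3, 3), 0, 100),
               "2 samples")
})

test_that("trapezoid layer mean matches a dense-grid numerical oracle", {
  oc <- simulate_ocean(seed = 42, noise = FALSE)
  s1 <- oc$samples[oc$samples$station == "st1" &
                     !is.na(oc$samples$cr_total_nmolkg), ]
  prof <- aggregate(cr_total_nmolkg ~ depth_m, data = s1, FUN = mean)
  got <- trapezoid_layer_mean(prof$depth_m, prof$cr_total_nmolkg, 0, 100)
  want <- fine_grid_layer_mean(prof$depth_m, prof$cr_total_nmolkg, 0, 100)
  expect_equal(got, want, tolerance = 0.01)
})

test_that("deficits compare layers and judge significance against precision", {
  z <- c(10, 50, 100, 150, 200)
  flat <- cr_deficit(z, rep(3, 5))
  expect_equal(flat$deficit_conc, 0)
  expect_false(flat$significant)

  # a station-1-scale deficit (0.27 nmol/kg on a 3.00 reference) is significant
  prof <- ifelse(z <= 100, 2.73, 3.00)
  d <- cr_deficit(z, prof)
  expect_equal(d$deficit_conc, 0.27, tolerance = 1e-9)
  expect_true(d$significant)

  # a 0.01 deficit is inside analytical noise
  prof2 <- ifelse(z <= 100, 2.99, 3.00)
  d2 <- cr_deficit(z, prof2)
  expect_equal(d2$deficit_conc, 0.01, tolerance = 1e-9)
  expect_false(d2$significant)

  # single-RSD rule is stricter about calling things significant
  expect_equal(cr_deficit(z, prof, rule = "single")$threshold,
               cr_deficit(z, prof)$threshold / sqrt(2))
})

test_that("areal deficits are reported both bulk and profile-integrated", {
  z <- c(10, 50, 100, 150, 200)
  prof <- ifelse(z <= 100, 2.73, 3.00)
  ar <- areal_deficit(z, prof, ml_depth = 19.2)
  expect_equal(ar$bulk, convert_conc_to_areal(0.27, 19.2), tolerance = 1e-9)
  # uniform depletion: the two constructions coincide
  expect_equal(ar$profile, ar$bulk, tolerance = 1e-9)
  # surface-concentrated depletion: profile-integrated exceeds bulk
  prof3 <- 3.0 - 0.4 * exp(-z / 15)
  ar3 <- areal_deficit(z, prof3, ml_depth = 30)
  expect_gt(ar3$profile, ar3$bulk)
})

test_that("inferred export spans the Cr:C bounds and formats to 1 sig fig", {
  expect_equal(unlist(inferred_export(0)), c(low = 0, high = 0))
  e1 <- inferred_export(3.02)
  expect_equal(e1$low, 3.02 * 0.555)
  expect_equal(e1$high, 3.02 * 2.7)
  expect_equal(format_export_range(e1), "2-8")
  expect_equal(format_export_range(inferred_export(0.29)), "0.2-0.8")
  expect_equal(format_export_range(inferred_export(2.22)), "1-6")
  expect_error(inferred_export(-1), "non-negative")
})

test_that("global export scales with carbon export and overlaps the sources", {
  g <- global_export(c(5, 5.7, 8))
  expect_equal(g$export_range[1] / 1e8, 2.3, tolerance = 0.01)
  expect_true(g$overlaps)
  deep <- global_export(0.43)
  expect_equal(deep$export_range / 1e8, c(0.2, 1.0), tolerance = 0.05)
  # monotone in both ANCP and Cr:C
  expect_true(all(diff(inferred_export(c(1, 2, 3))$low) > 0))
  expect_lt(global_export(2)$export_range[2], global_export(4)$export_range[2])
})

test_that("measured deficits recover export imposed over one seasonal cycle", {
  cfg <- cr_sim_config(cr3_ncp_slope = 0, cr3_base = 0.15,
                       crc_export = 2, drawdown_years = 1)
  oc <- simulate_ocean(cfg, seed = 43, noise = FALSE)
  rho <- cr_constants()$density_sw
  for (i in seq_len(cfg$n_stations)) {
    st <- paste0("st", i)
    prof <- oc$samples[oc$samples$station == st &
                         !is.na(oc$samples$cr_total_nmolkg), ]
    d <- cr_deficit(prof$depth_m, prof$cr_total_nmolkg)
    imposed <- cfg$ancp[i] * 2 * 1e-6 / (100 * rho) * 1e9  # nmol/kg over 100 m
    expect_equal(d$deficit_conc, imposed, tolerance = 0.10)
  }
})

test_that("the budget table mirrors the station summary layout", {
  oc <- simulate_ocean(seed = 44)
  bt <- budget_table(oc$samples, oc$contexts)
  expect_equal(nrow(bt), 6)
  expect_true(all(c("deficit_nmolkg", "significant", "areal_deficit_umol_m2",
                    "export_low", "export_high", "export_range") %in% names(bt)))
  # high-productivity subarctic stations show significant deficits,
  # the oligotrophic gyre does not
  expect_true(bt$significant[bt$station == "st1"])
  expect_false(bt$significant[bt$station == "st6"])
})
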