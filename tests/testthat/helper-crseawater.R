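# shared fixtures and independent oracles

# dense-grid numerical layer mean, independent of the trapezoid implementation
fine_grid_layer_mean <- function(depth, conc, z_top, z_bottom, n = 20001) {
  f <- approxfun(depth, conc, rule = 2)
  z <- seq(z_top, z_bottom, length.out = n)
  mean(f(z))
}

# central finite-difference Jacobian of the double-spike forward model
fd_jacobian <- function(lambda, alpha, beta, system, h = 1e-6) {
  th <- c(lambda, alpha, beta)
  sapply(1:3, function(j) {
    tp <- th; tm <- th
    tp[j] <- tp[j] + h; tm[j] <- tm[j] - h
    (spike_forward(tp[1], tp[2], tp[3], system) -
       spike_forward(tm[1], tm[2], tm[3], system)) / (2 * h)
  })
}

# solve the self-consistent mass-balance mixing relation numerically for
# delta_total at Cr(III) = x: delta = (dvi*C + (delta + dcap)*x) / (C + x)
implicit_mixing_delta <- function(x, dvi, dcap, C) {
  vapply(x, function(xi) {
    uniroot(function(d) d - (dvi * C + (d + dcap) * xi) / (C + xi),
            interval = c(dvi - 10, dvi + 10), tol = 1e-12)$root
  }, numeric(1))
}

# mixing with a fixed Cr(III) pool composition (genuinely hyperbolic in x)
fixed_pool_mixing_delta <- function(x, dvi, d3, C) {
  (dvi * C + d3 * x) / (C + x)
}

write_toy_station_csv <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      station = c("a", "a", "b"), lat = c(50, 50, 40),
      depth_m = c(10, 100, 10), time_local = c("06:00", "06:00", "12:00"),
      cr_total_nmolkg = c(2.95, 3.01, 3.10), cr_total_sd = c(0.02, 0.02, 0.03),
      d53cr_permil = c(1.10, 1.05, 1.15), d53cr_2se = c(0.03, 0.03, 0.03),
      cr3_nmolkg = c(0.21, 0.12, 0.15), cr3_sd = c(0.02, 0.01, 0.02),
      replicate = c(1, 1, 1), day = c(1, 1, 1))
  }
  write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  rows
}
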