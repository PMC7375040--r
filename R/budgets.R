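#' Trapezoidal layer-mean concentration
#'
#' Integrates a discrete depth profile over `[z_top, z_bottom]` by the
#' trapezoid rule and divides by the layer thickness. The shallowest sample is
#' extended uniformly up to `z_top`; the deepest sample in range is linearly
#' interpolated to `z_bottom` when a deeper sample exists, otherwise extended
#' uniformly. Exact for piecewise-linear profiles sampled at the nodes.
#'
#' @param depth sample depths, m (positive down).
#' @param conc concentrations at `depth`, nmol/kg.
#' @param z_top,z_bottom layer bounds, m (`z_top < z_bottom`).
#' @return layer-mean concentration, nmol/kg.
#' @export
#' @examples
#' trapezoid_layer_mean(c(0, 50, 100), c(2, 2.5, 3), 0, 100)  # 2.5
trapezoid_layer_mean <- function(depth, conc, z_top, z_bottom) {
  stopifnot(length(depth) == length(conc), z_top < z_bottom)
  ok <- !is.na(depth) & !is.na(conc)
  depth <- depth[ok]; conc <- conc[ok]
  o <- order(depth)
  depth <- depth[o]; conc <- conc[o]
  cfun <- stats::approxfun(depth, conc, rule = 2, ties = mean)
  inside <- depth > z_top & depth < z_bottom
  n_in <- sum(depth >= z_top & depth <= z_bottom)
  # one interior sample suffices when a deeper sample brackets the layer for
  # interpolation; otherwise the layer is undersampled
  if (n_in < 2 && !(n_in >= 1 && any(depth > z_bottom)))
    stop("need at least 2 samples intersecting the layer")
  nodes <- sort(unique(c(z_top, depth[inside], z_bottom)))
  v <- cfun(nodes)
  area <- sum(diff(nodes) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  area / (z_bottom - z_top)
}

#' Mixed-layer Cr concentration deficit and its significance
#'
#' The upper-ocean Cr deficit is the trapezoid-mean `[Cr]` over the reference
#' layer (default 150-200 m) minus the trapezoid-mean over the upper layer
#' (default 0-100 m, the approximate winter mixed layer). The deficit is
#' called significant when it exceeds the combined analytical 1 RSD of the two
#' layer means: `sqrt(2) * rsd * ref_mean` by default, or `rsd * ref_mean`
#' with `rule = "single"`.
#'
#' @param depth,conc the `[Cr]` depth profile (nmol/kg).
#' @param upper,ref numeric length-2 layer bounds, m.
#' @param rsd relative 1 SD of the concentration measurement (default 0.82%).
#' @param rule `"combined"` (default) or `"single"` significance rule.
#' @return list with `mean_upper`, `mean_ref`, `deficit_conc` (nmol/kg),
#'   `threshold`, `significant`.
#' @export
cr_deficit <- function(depth, conc, upper = c(0, 100), ref = c(150, 200),
                       rsd = cr_constants()$rsd_cr,
                       rule = c("combined", "single")) {
  rule <- match.arg(rule)
  mu <- trapezoid_layer_mean(depth, conc, upper[1], upper[2])
  mr <- trapezoid_layer_mean(depth, conc, ref[1], ref[2])
  d <- mr - mu
  thr <- (if (rule == "combined") sqrt(2) else 1) * rsd * mr
  list(mean_upper = mu, mean_ref = mr, deficit_conc = d,
       threshold = thr, significant = d > thr)
}

#' Areal mixed-layer Cr deficit, computed two ways
#'
#' Converts a concentration deficit to an areal deficit (umol/m2) over the
#' on-station mixed layer. Two constructions are reported because they answer
#' slightly different questions and need not agree on structured profiles:
#' `bulk` multiplies the (reference-minus-upper-layer) concentration deficit
#' by the mixed-layer thickness and density; `profile` integrates
#' `ref_mean - c(z)` over the mixed layer itself, which weights the actual
#' near-surface depletion.
#'
#' @param depth,conc the `[Cr]` profile (nmol/kg).
#' @param ml_depth on-station mixed-layer depth, m.
#' @param deficit a [cr_deficit()] result for this profile (computed if
#'   omitted).
#' @param density seawater density, kg/m3.
#' @param ... passed to [cr_deficit()].
#' @return list with `bulk` and `profile` areal deficits, umol/m2 (negative
#'   values indicate surplus and are reported as-is).
#' @export
areal_deficit <- function(depth, conc, ml_depth, deficit = NULL,
                          density = cr_constants()$density_sw, ...) {
  if (is.null(deficit)) deficit <- cr_deficit(depth, conc, ...)
  bulk <- convert_conc_to_areal(deficit$deficit_conc, ml_depth, density)
  ml_mean <- trapezoid_layer_mean(depth, conc, 0, ml_depth)
  profile <- convert_conc_to_areal(deficit$mean_ref - ml_mean, ml_depth, density)
  list(bulk = bulk, profile = profile)
}

#' Cr export inferred from annual net community productivity
#'
#' Multiplies ANCP by the bounding phytoplankton / sinking-particle Cr:C
#' ratios. Values are returned at full precision; `format_export_range()`
#' renders the 1-significant-figure presentation used in summary tables.
#'
#' @param ancp annual net community productivity, mol C m-2 yr-1 (>= 0).
#'   Vectorised.
#' @param crc_low,crc_high Cr:C bounds, umol Cr per mol C.
#' @return `data.frame` with `low` and `high`, umol Cr m-2 yr-1.
#' @export
#' @examples
#' inferred_export(3.02)                  # station-1-style ANCP
#' format_export_range(inferred_export(3.02))  # "2-8"
inferred_export <- function(ancp, crc_low = cr_constants()$crc_low,
                            crc_high = cr_constants()$crc_high) {
  if (any(ancp < 0)) stop("ancp must be non-negative")
  stopifnot(crc_low <= crc_high)
  data.frame(low = ancp * crc_low, high = ancp * crc_high)
}

#' @rdname inferred_export
#' @param range a `data.frame` with `low`/`high` columns.
#' @export
format_export_range <- function(range) {
  fmt <- function(v) {
    s <- signif(v, 1)
    ifelse(s == round(s), format(as.integer(round(s))), format(s))
  }
  paste0(fmt(range$low), "-", fmt(range$high))
}

#' Global biological Cr export and comparison with Cr sources
#'
#' Scales global carbon export estimates (GT C/yr) by the Cr:C bounds to a
#' global Cr export range (mol Cr/yr) and compares it with the magnitude of
#' Cr sources to the ocean (default: the riverine-dominated source flux
#' 0.5-5.6e8 mol Cr/yr).
#'
#' @param c_export one or more global C export estimates, GT C/yr.
#' @param crc_low,crc_high Cr:C bounds, umol Cr per mol C.
#' @param source_range Cr source flux range, mol Cr/yr.
#' @return list with `export_range` (mol Cr/yr), `source_range`, and
#'   logical `overlaps`.
#' @export
#' @examples
#' global_export(c(5, 5.7, 8))
global_export <- function(c_export, crc_low = cr_constants()$crc_low,
                          crc_high = cr_constants()$crc_high,
                          source_range = c(0.5e8, 5.6e8)) {
  if (any(c_export <= 0)) stop("c_export must be positive")
  combos <- as.vector(outer(c_export, c(crc_low, crc_high),
                            gigatons_c_to_mol_cr))
  er <- range(combos)
  list(export_range = er, source_range = source_range,
       overlaps = er[1] <= source_range[2] && er[2] >= source_range[1])
}

#' Per-station budget table
#'
#' Runs [cr_deficit()], [areal_deficit()] and [inferred_export()] for every
#' station in a sample table, mirroring the layout of a station-by-station
#' export comparison: concentration deficit and significance, areal deficit
#' over the on-station mixed layer, ANCP, and the inferred Cr export range.
#'
#' @param samples station table with `station`, `depth_m`, `cr_total_nmolkg`.
#' @param contexts station contexts (see [read_station_contexts()]).
#' @param constants a [cr_constants()] list.
#' @param ... passed to [cr_deficit()].
#' @return `data.frame`, one row per station. Stations whose profiles do not
#'   reach the reference layer get `NA` deficits.
#' @export
budget_table <- function(samples, contexts, constants = cr_constants(), ...) {
  rows <- lapply(seq_len(nrow(contexts)), function(i) {
    st <- contexts$station[i]
    prof <- samples[samples$station == st & !is.na(samples$cr_total_nmolkg), ]
    prof <- stats::aggregate(cr_total_nmolkg ~ depth_m, data = prof, FUN = mean)
    out <- data.frame(station = st, lat = if ("lat" %in% names(contexts))
      contexts$lat[i] else NA_real_,
      deficit_nmolkg = NA_real_, significant = NA,
      ml_m = contexts$obs_ml_depth_m[i],
      areal_deficit_umol_m2 = NA_real_,
      ancp_molc_m2_yr = contexts$ancp_molc_m2_yr[i],
      stringsAsFactors = FALSE)
    ok <- tryCatch({
      dfc <- cr_deficit(prof$depth_m, prof$cr_total_nmolkg,
                        rsd = constants$rsd_cr, ...)
      ar <- areal_deficit(prof$depth_m, prof$cr_total_nmolkg,
                          ml_depth = contexts$obs_ml_depth_m[i],
                          deficit = dfc, density = constants$density_sw)
      out$deficit_nmolkg <- dfc$deficit_conc
      out$significant <- dfc$significant
      out$areal_deficit_umol_m2 <- ar$bulk
      TRUE
    }, error = function(e) FALSE)
    ex <- inferred_export(contexts$ancp_molc_m2_yr[i],
                          constants$crc_low, constants$crc_high)
    out$export_low <- ex$low
    out$export_high <- ex$high
    out$export_range <- format_export_range(ex)
    out
  })
  do.call(rbind, rows)
}
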