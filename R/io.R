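#' Read a station sample table
#'
#' Reads one bottle-replicate per row from a comma-separated file with a header
#' row. Required columns: `station`, `depth_m`, `cr_total_nmolkg`. Optional
#' columns (`lat`, `time_local`, `cr_total_sd`, `d53cr_permil`, `d53cr_2se`,
#' `cr3_nmolkg`, `cr3_sd`, `replicate`, `day`) are filled with `NA` when
#' absent. Unparseable numeric cells become `NA` with a warning; negative
#' concentrations are a validation error naming the offending row.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` with one row per bottle replicate and the canonical
#'   column set (`station`, `lat`, `depth_m`, `time_local`, `cr_total_nmolkg`,
#'   `cr_total_sd`, `d53cr_permil`, `d53cr_2se`, `cr3_nmolkg`, `cr3_sd`,
#'   `replicate`, `day`), row order preserved.
#' @seealso [write_station_table()], [read_station_contexts()]
#' @export
read_station_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("station", "depth_m", "cr_total_nmolkg")
  missing <- setdiff(required, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))

  numeric_cols <- c("lat", "depth_m", "cr_total_nmolkg", "cr_total_sd",
                    "d53cr_permil", "d53cr_2se", "cr3_nmolkg", "cr3_sd")
  optional <- c("lat", "time_local", "cr_total_sd", "d53cr_permil", "d53cr_2se",
                "cr3_nmolkg", "cr3_sd", "replicate", "day")
  for (col in optional) if (!col %in% names(raw)) raw[[col]] <- NA

  for (col in intersect(numeric_cols, names(raw))) {
    v <- raw[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- !is.na(v) & v != "" & is.na(parsed)
      if (any(bad))
        warning(sum(bad), " unparseable value(s) in column '", col,
                "' set to NA", call. = FALSE)
      raw[[col]] <- parsed
    }
  }

  out <- raw[c("station", "lat", "depth_m", "time_local", "cr_total_nmolkg",
               "cr_total_sd", "d53cr_permil", "d53cr_2se", "cr3_nmolkg",
               "cr3_sd", "replicate", "day")]
  validate_station_table(out)
  out
}

validate_station_table <- function(df) {
  check_nonneg <- function(col, label) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad))
      stop("negative ", label, " in row(s) ", paste(bad, collapse = ", "))
  }
  check_nonneg("depth_m", "depth")
  check_nonneg("cr_total_nmolkg", "[Cr]")
  check_nonneg("cr3_nmolkg", "[Cr(III)]")
  # Cr(III) may not exceed total Cr beyond combined 2 sigma
  both <- !is.na(df$cr3_nmolkg) & !is.na(df$cr_total_nmolkg)
  if (any(both)) {
    s_tot <- ifelse(is.na(df$cr_total_sd), 0, df$cr_total_sd)
    s_cr3 <- ifelse(is.na(df$cr3_sd), 0, df$cr3_sd)
    lim <- df$cr_total_nmolkg + 2 * sqrt(s_tot^2 + s_cr3^2)
    bad <- which(both & df$cr3_nmolkg > lim)
    if (length(bad))
      stop("[Cr(III)] exceeds [Cr] beyond combined 2 sigma in row(s) ",
           paste(bad, collapse = ", "))
  }
  invisible(df)
}

#' Write a station sample table
#'
#' Inverse of [read_station_table()]; the read-write-read round trip is
#' lossless for all typed fields.
#'
#' @param df a station table `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_station_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read per-station context metadata
#'
#' Station contexts carry the depths and productivity numbers the budget and
#' fit selections need: the winter mixed-layer depth (integration reference,
#' default 100 m), the observed mixed-layer depth while on station, the
#' euphotic depth (1% isolume) and NCP/ANCP. A warning (not an error) is
#' issued when the on-station mixed layer exceeds the winter mixed layer.
#'
#' @param path CSV with columns `station`, `obs_ml_depth_m`,
#'   `euphotic_depth_m`, `ancp_molc_m2_yr` and optional `lat`,
#'   `winter_ml_depth_m`, `ncp_vol_mmolc_m3_d`.
#' @return `data.frame` of station contexts.
#' @export
read_station_contexts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("station", "obs_ml_depth_m", "euphotic_depth_m", "ancp_molc_m2_yr")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (!"winter_ml_depth_m" %in% names(df)) df$winter_ml_depth_m <- 100
  if (!"ncp_vol_mmolc_m3_d" %in% names(df)) df$ncp_vol_mmolc_m3_d <- NA_real_
  if (any(df$euphotic_depth_m <= 0)) stop("euphotic_depth_m must be positive")
  if (any(df$obs_ml_depth_m <= 0)) stop("obs_ml_depth_m must be positive")
  deep <- df$obs_ml_depth_m > df$winter_ml_depth_m
  if (any(deep))
    warning("on-station mixed layer deeper than winter mixed layer at station(s) ",
            paste(df$station[deep], collapse = ", "), call. = FALSE)
  df
}
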