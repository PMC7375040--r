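#' Modified Thompson tau outlier test
#'
#' Iterative one-at-a-time rejection: at each step the single largest absolute
#' deviation from the current mean is compared against
#' \deqn{\tau \cdot s, \quad \tau = \frac{t \, (n-1)}{\sqrt{n}\sqrt{n-2+t^2}}}
#' where \eqn{t} is the two-sided critical value of Student's t at `alpha`
#' with \eqn{n-2} degrees of freedom and \eqn{s} the sample SD. The flagged
#' point is removed and the procedure repeats on the remainder until no
#' deviation exceeds the threshold, or fewer than 3 points remain. The test is
#' symmetric: low outliers are eligible even though field contamination tends
#' to produce only high ones.
#'
#' By default `alpha` is interpreted per group: the critical value uses
#' `alpha / (2n)` (a Bonferroni share per point), which keeps the chance of
#' flagging anything in an uncontaminated Gaussian group near `alpha`. The
#' engineering-handbook variant, which applies the two-sided `alpha` directly
#' to the extreme deviation and rejects far more aggressively on clean data,
#' is available with `per_point = TRUE`.
#'
#' Iteration order: the classic form (`iteration = "outward"`) tests and
#' removes the single largest deviation repeatedly. With several clustered
#' outliers that form masks itself (the cluster inflates the SD so the first
#' test never fires). The default `"inward"` order removes the most deviant
#' half (judged from the median) provisionally and then reinstates points,
#' closest first, whenever they pass the same tau criterion against the
#' retained set — identical on single outliers, robust to clusters.
#'
#' @param values numeric vector of replicate measurements.
#' @param alpha significance level (default 0.05).
#' @param per_point use the uncorrected per-point critical value (see
#'   Details).
#' @param iteration `"inward"` (masking-robust, default) or `"outward"`
#'   (classic one-at-a-time).
#' @return logical vector the length of `values`; `TRUE` marks an outlier.
#'   With fewer than 3 values no rejection is attempted (all `FALSE`). At
#'   most half the points (rounded up) can be rejected.
#' @export
#' @examples
#' modified_thompson_tau(c(0.10, 0.11, 0.09, 0.45))
modified_thompson_tau <- function(values, alpha = 0.05, per_point = FALSE,
                                  iteration = c("inward", "outward")) {
  stopifnot(is.numeric(values), alpha > 0, alpha < 1)
  iteration <- match.arg(iteration)
  if (anyNA(values)) stop("values must not contain NA")
  n0 <- length(values)
  mask <- rep(FALSE, n0)
  if (n0 < 3) return(mask)

  tau_threshold <- function(n) {
    a_eff <- if (per_point) alpha / 2 else alpha / (2 * n)
    tcrit <- stats::qt(1 - a_eff, df = n - 2)
    tcrit * (n - 1) / (sqrt(n) * sqrt(n - 2 + tcrit^2))
  }
  # outward single test on the set x: index of rejected point or 0
  test_extreme <- function(x) {
    s <- stats::sd(x)
    if (s == 0) return(0L)
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    if (dev[i] > tau_threshold(length(x)) * s) i else 0L
  }

  # keep at least 3 retained points: reinstatement pools of 3 sit exactly at
  # the tau criterion's attainable maximum and are numerically degenerate
  max_reject <- min(ceiling(n0 / 2), n0 - 3)
  if (max_reject < 1) return(mask)
  if (iteration == "outward") {
    repeat {
      keep <- which(!mask)
      if (sum(mask) >= max_reject || length(keep) < 3) break
      i <- test_extreme(values[keep])
      if (i == 0L) break
      mask[keep[i]] <- TRUE
    }
    return(mask)
  }

  # inward: provisionally drop the most deviant points (from the median),
  # then reinstate any that pass the tau test against the retained set
  dev_med <- abs(values - stats::median(values))
  out <- order(dev_med, decreasing = TRUE)[seq_len(max_reject)]
  mask[out] <- TRUE
  repeat {
    keep <- which(!mask)
    cand <- which(mask)
    if (!length(cand)) break
    # candidate closest to the retained mean first
    cand <- cand[order(abs(values[cand] - mean(values[keep])))]
    reinstated <- FALSE
    for (j in cand) {
      pool <- c(values[keep], values[j])
      s <- stats::sd(pool)
      dev <- abs(values[j] - mean(pool))
      if (s == 0 || dev <= tau_threshold(length(pool)) * s) {
        mask[j] <- FALSE
        reinstated <- TRUE
        break
      }
    }
    if (!reinstated) break
  }
  mask
}

#' Aggregate diel replicate measurements
#'
#' Groups a station table by station, depth and (optionally) day, rejects
#' outliers within each group with [modified_thompson_tau()], and returns the
#' group mean and 1 SD over the surviving replicates. Groups with a single
#' value receive a conservative relative uncertainty (default 10%) instead of
#' an SD; groups with two or more surviving values are flagged
#' `diel_replicated`.
#'
#' @param df station table (see [read_station_table()]) or any `data.frame`
#'   with `station`, `depth_m` and a value column.
#' @param value column name holding the replicate measurements
#'   (default `"cr3_nmolkg"`).
#' @param alpha significance level passed to [modified_thompson_tau()].
#' @param by_day if `TRUE` and a `day` column exists, groups are split by day
#'   (used e.g. where consecutive days sampled different water).
#' @param single_rel_unc relative 1-sigma assigned to single-value groups.
#' @return `data.frame` with one row per group: `station`, `depth_m`,
#'   (`day`,) `n`, `n_used`, `mean`, `sd`, `n_outliers`, `diel_replicated`,
#'   plus a list-column `outlier_mask`.
#' @export
aggregate_diel <- function(df, value = "cr3_nmolkg", alpha = 0.05,
                           by_day = FALSE, single_rel_unc = 0.10) {
  stopifnot(is.data.frame(df), value %in% names(df))
  use <- !is.na(df[[value]])
  if (!any(use)) stop("no non-missing values to aggregate")
  d <- df[use, , drop = FALSE]
  keys <- list(station = d$station, depth_m = d$depth_m)
  if (by_day) {
    if (!"day" %in% names(d)) stop("by_day = TRUE requires a 'day' column")
    keys$day <- d$day
  }
  idx <- split(seq_len(nrow(d)), keys, drop = TRUE)
  rows <- lapply(idx, function(i) {
    x <- d[[value]][i]
    mask <- modified_thompson_tau(x, alpha = alpha)
    xs <- x[!mask]
    out <- data.frame(
      station = d$station[i[1]],
      depth_m = d$depth_m[i[1]],
      n = length(x),
      n_used = length(xs),
      mean = mean(xs),
      sd = if (length(xs) >= 2) stats::sd(xs) else mean(xs) * single_rel_unc,
      n_outliers = sum(mask),
      diel_replicated = length(xs) >= 2,
      stringsAsFactors = FALSE
    )
    if (by_day) out$day <- d$day[i[1]]
    out$outlier_mask <- I(list(mask))
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$station, res$depth_m), , drop = FALSE]
}

#' Test for a 24-hour cycle in replicate time series
#'
#' Least-squares fit of a sinusoid with fixed 24-h period,
#' `y ~ sin(2*pi*t/24) + cos(2*pi*t/24)`, to values with local-time stamps.
#' The amplitude is `sqrt(a^2 + b^2)` with a delta-method standard error;
#' significance is judged by the F test of the two sinusoid terms against the
#' constant model, which holds the false-positive rate at `alpha` (an
#' "amplitude exceeds 2 SE" rule is anti-conservative, since the amplitude is
#' a norm and cannot be negative).
#'
#' @param times sample times, hours (any origin).
#' @param values measurements at `times`.
#' @param alpha significance level of the F test.
#' @return list with `amplitude`, `se`, `p_value`, `significant`, `phase_h`
#'   and the underlying `lm` fit.
#' @export
detect_diel_cycle <- function(times, values, alpha = 0.05) {
  stopifnot(length(times) == length(values))
  ok <- !is.na(times) & !is.na(values)
  times <- times[ok]; values <- values[ok]
  if (length(times) < 4) stop("need at least 4 time points")
  if (diff(range(times)) < 24)
    stop("time series must span at least one 24-h period")
  s <- sin(2 * pi * times / 24)
  c_ <- cos(2 * pi * times / 24)
  fit <- stats::lm(values ~ s + c_)
  ab <- stats::coef(fit)[c("s", "c_")]
  V <- stats::vcov(fit)[c("s", "c_"), c("s", "c_")]
  amp <- sqrt(sum(ab^2))
  # delta method: grad = ab / amp
  se <- if (amp > 0) sqrt(drop(t(ab / amp) %*% V %*% (ab / amp))) else sqrt(V[1, 1])
  f0 <- stats::lm(values ~ 1)
  p <- stats::anova(f0, fit)[["Pr(>F)"]][2]
  list(amplitude = unname(amp), se = unname(se), p_value = p,
       significant = is.finite(p) && p < alpha,
       phase_h = unname(atan2(ab[1], ab[2]) * 24 / (2 * pi)),
       fit = fit)
}
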