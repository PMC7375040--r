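#' Fit the seawater Cr isotope fractionation model
#'
#' The central fitted-model interface of the package. Two modes:
#' \describe{
#'   \item{`mode = "cr3"`}{total dissolved delta-53Cr against reactive
#'     \eqn{[Cr(III)]}. Under the two-pool mass balance
#'     \deqn{[Cr] = [Cr(VI)+Cr(III)_{NR}] + [Cr(III)]}
#'     \deqn{\delta^{53}Cr \cdot [Cr] = \delta_{VI+NR} \cdot [Cr(VI)+Cr(III)_{NR}]
#'       + \delta_{III} \cdot [Cr(III)]}
#'     with the background pool held constant at `cr6nr_const`, a linear trend
#'     of delta-53Cr in \eqn{[Cr(III)]} implies the intercept is
#'     \eqn{\delta_{VI+NR}} (the \eqn{[Cr(III)] \to 0} limit) and the isotopic
#'     offset of the Cr(III) being added or removed relative to the total pool
#'     is \eqn{\Delta^{53}Cr = slope \times cr6nr\_const}, constant along the
#'     trend.}
#'   \item{`mode = "lncr"`}{delta-53Cr against \eqn{\ln[Cr]}: the Rayleigh-style
#'     global trend whose slope is the isotope enrichment factor \eqn{\epsilon}.}
#' }
#'
#' The default fit is unweighted ordinary least squares (a simple linear fit).
#' When 1-sigma uncertainties are supplied on both axes, `method = "york"`
#' performs the York errors-in-variables fit. 95% confidence intervals use the
#' t distribution with n-2 degrees of freedom.
#'
#' @param x predictor: \eqn{[Cr(III)]} nmol/kg (`mode = "cr3"`) or \eqn{[Cr]}
#'   nmol/kg (`mode = "lncr"`; the log is taken internally, so all values must
#'   be positive). Alternatively a formula `delta ~ conc` with `data`.
#' @param y response delta-53Cr, permil (ignored when `x` is a formula).
#' @param sx,sy optional per-point 1-sigma on `x` and `y`. For `mode = "lncr"`
#'   `sx` is interpreted as a *relative* sigma on [Cr] (sigma of ln[Cr]).
#' @param data `data.frame` for the formula interface.
#' @param mode `"cr3"` or `"lncr"` (see Details).
#' @param method `"ols"` (default) or `"york"` (requires `sx` and `sy`).
#' @param cr6nr_const background \eqn{[Cr(VI)+Cr(III)_{NR}]}, nmol/kg.
#' @return An object of class `"cr_fracfit"`: a list with `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `ci95_slope`, `ci95_intercept`,
#'   `r2`, `n`, `method`, `mode`, and the derived quantities `delta_vi_nr`,
#'   `delta_cap`, `delta_cap_ci` (mode "cr3") or `epsilon`, `epsilon_ci`
#'   (mode "lncr"). Supports `print`, `summary`, `coef`, `confint`,
#'   `predict`, `residuals` and `plot`.
#' @export
#' @examples
#' x <- c(0.05, 0.1, 0.15, 0.2, 0.3)
#' y <- 1.178 - 1.08 / 2.9 * x
#' fit <- cr_fractionation(x, y)
#' coef(fit)
#' fit$delta_cap   # -1.08
cr_fractionation <- function(x, y = NULL, sx = NULL, sy = NULL, data = NULL,
                             mode = c("cr3", "lncr"),
                             method = c("ols", "york"),
                             cr6nr_const = cr_constants()$cr6nr_const) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  cl <- match.call()
  if (inherits(x, "formula")) {
    mf <- stats::model.frame(x, data = data)
    y <- mf[[1L]]
    x <- mf[[2L]]
  }
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok)) { x <- x[ok]; y <- y[ok]
    if (!is.null(sx)) sx <- sx[ok]
    if (!is.null(sy)) sy <- sy[ok] }
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  xin <- x
  if (mode == "lncr") {
    if (any(x <= 0)) stop("concentrations must be positive for mode 'lncr'")
    x <- log(x)
  }
  if (stats::var(x) == 0) stop("zero variance in predictor")
  if (method == "york" && (is.null(sx) || is.null(sy)))
    stop("method 'york' requires sx and sy")

  if (method == "ols") {
    X <- cbind(1, x)
    xtx_inv <- solve(crossprod(X))
    dimnames(xtx_inv) <- NULL
    ab <- drop(xtx_inv %*% crossprod(X, y))
    a <- unname(ab[1]); b <- unname(ab[2])
    res <- y - a - b * x
    s2 <- sum(res^2) / (n - 2)
    vcov_ab <- s2 * xtx_inv
    se_a <- sqrt(vcov_ab[1, 1]); se_b <- sqrt(vcov_ab[2, 2])
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  } else {
    yk <- york_fit(x, y, rep_len(sx, n), rep_len(sy, n))
    a <- yk$intercept; b <- yk$slope
    se_a <- yk$se_intercept; se_b <- yk$se_slope
    r2 <- stats::cor(x, y)^2
    vcov_ab <- matrix(c(se_a^2, yk$cov_ab, yk$cov_ab, se_b^2), 2)
  }
  tq <- stats::qt(0.975, df = n - 2)
  obj <- list(
    slope = b, intercept = a, se_slope = se_b, se_intercept = se_a,
    ci95_slope = c(b - tq * se_b, b + tq * se_b),
    ci95_intercept = c(a - tq * se_a, a + tq * se_a),
    r2 = r2, n = n, method = method, mode = mode,
    cr6nr_const = cr6nr_const, vcov = vcov_ab,
    x = x, y = y, x_input = xin, sx = sx, sy = sy,
    fitted = a + b * x, residuals = y - (a + b * x),
    df.residual = n - 2, call = cl
  )
  if (mode == "cr3") {
    mb <- mass_balance_delta_iii(obj, cr6nr_const)
    obj$delta_vi_nr <- mb$delta_vi_nr
    obj$delta_cap <- mb$delta_cap
    obj$delta_cap_ci <- mb$delta_cap_ci
  } else {
    obj$epsilon <- b
    obj$epsilon_ci <- obj$ci95_slope
  }
  class(obj) <- "cr_fracfit"
  obj
}

# York (1966/2004) errors-in-variables straight line, uncorrelated errors.
york_fit <- function(x, y, sx, sy, tol = 1e-12, maxit = 200) {
  wx <- 1 / sx^2; wy <- 1 / sy^2
  b <- stats::coef(stats::lm(y ~ x))[2]
  for (it in seq_len(maxit)) {
    W <- wx * wy / (b^2 * wy + wx)
    xbar <- sum(W * x) / sum(W); ybar <- sum(W * y) / sum(W)
    U <- x - xbar; V <- y - ybar
    beta <- W * (U / wy + b * V / wx)
    b_new <- sum(W * beta * V) / sum(W * beta * U)
    if (abs(b_new - b) < tol * max(1, abs(b))) { b <- b_new; break }
    b <- b_new
  }
  W <- wx * wy / (b^2 * wy + wx)
  xbar <- sum(W * x) / sum(W); ybar <- sum(W * y) / sum(W)
  a <- ybar - b * xbar
  beta <- W * ((x - xbar) / wy + b * (y - ybar) / wx)
  x_adj <- xbar + beta
  xm <- sum(W * x_adj) / sum(W)
  u <- x_adj - xm
  var_b <- 1 / sum(W * u^2)
  var_a <- 1 / sum(W) + xm^2 * var_b
  list(slope = unname(b), intercept = unname(a),
       se_slope = sqrt(var_b), se_intercept = sqrt(var_a),
       cov_ab = -xm * var_b)
}

#' Isotope mass balance for Cr(III) addition/removal
#'
#' Given a fitted delta-53Cr vs \eqn{[Cr(III)]} trend and a constant
#' background pool \eqn{C = [Cr(VI)+Cr(III)_{NR}]}, the mass balance gives the
#' background composition \eqn{\delta_{VI+NR} = } intercept and the offset of
#' the Cr(III) pool relative to the total,
#' \eqn{\Delta^{53}Cr = slope \times C}, constant along the linear trend.
#'
#' @param fit a `"cr_fracfit"` (mode "cr3") or any list with `slope`,
#'   `intercept`, `se_slope`, `n`, `vcov` elements.
#' @param cr6nr_const the constant background pool C, nmol/kg.
#' @param ci how to form the 95% CI on Delta-53Cr: `"slope_ci"` scales the
#'   slope CI by C (default); `"monte_carlo"` propagates the joint sampling
#'   distribution of (intercept, slope) by simulation (identical here up to
#'   Monte-Carlo error, since Delta depends on the slope alone, but reported
#'   for completeness).
#' @param nsim Monte-Carlo draws for `ci = "monte_carlo"`.
#' @return list with `delta_vi_nr` (permil), `delta_cap` (permil),
#'   `delta_cap_ci` (length-2), `delta_iii_at` (function of \eqn{[Cr(III)]}
#'   returning the implied \eqn{\delta_{III}}).
#' @export
mass_balance_delta_iii <- function(fit, cr6nr_const = cr_constants()$cr6nr_const,
                                   ci = c("slope_ci", "monte_carlo"),
                                   nsim = 10000) {
  ci <- match.arg(ci)
  if (is.null(cr6nr_const) || !is.finite(cr6nr_const))
    stop("cr6nr_const is required")
  b <- fit$slope; a <- fit$intercept
  delta_cap <- b * cr6nr_const
  tq <- stats::qt(0.975, df = fit$n - 2)
  if (ci == "slope_ci") {
    hw <- tq * fit$se_slope * cr6nr_const
    cap_ci <- c(delta_cap - hw, delta_cap + hw)
  } else {
    L <- chol(fit$vcov)
    z <- matrix(stats::rnorm(2 * nsim), ncol = 2) %*% L
    draws <- (b + z[, 2]) * cr6nr_const
    cap_ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  }
  list(delta_vi_nr = a, delta_cap = delta_cap, delta_cap_ci = cap_ci,
       delta_iii_at = function(cr3) a + b * (cr6nr_const + cr3))
}

#' Back-compute the Cr(III) isotope composition from the mass balance
#'
#' Solves the isotope mass balance for \eqn{\delta_{III}} given the total
#' pool, its composition, the Cr(III) concentration and the background
#' composition: \eqn{\delta_{III} = (\delta \cdot [Cr] - \delta_{VI+NR} \cdot
#' ([Cr]-[Cr(III)])) / [Cr(III)]}.
#'
#' @param d53_total total dissolved delta-53Cr, permil.
#' @param cr_total total dissolved Cr, nmol/kg.
#' @param cr3 Cr(III), nmol/kg (> 0).
#' @param delta_vi_nr background composition, permil.
#' @return implied delta-53Cr of the Cr(III) pool, permil.
#' @export
delta_iii_mass_balance <- function(d53_total, cr_total, cr3, delta_vi_nr) {
  if (any(cr3 <= 0)) stop("cr3 must be positive")
  (d53_total * cr_total - delta_vi_nr * (cr_total - cr3)) / cr3
}

#' Global Rayleigh-style enrichment factor from delta-53Cr and ln[Cr]
#'
#' Convenience wrapper around [cr_fractionation()] with `mode = "lncr"`: an
#' OLS (or, with uncertainties, York) fit of delta-53Cr on \eqn{\ln[Cr]}
#' whose slope is the isotope enrichment factor \eqn{\epsilon}.
#'
#' @param cr total dissolved Cr, nmol/kg (> 0).
#' @param d53 delta-53Cr, permil.
#' @param sd_d53 optional per-point 1-sigma on delta-53Cr; supplying it
#'   switches to the errors-in-variables fit with a relative sigma on [Cr].
#' @param cr_rel_sd relative 1-sigma assumed for [Cr] (default 1%).
#' @return `"cr_fracfit"` with `epsilon` and `epsilon_ci`.
#' @export
fit_global_epsilon <- function(cr, d53, sd_d53 = NULL, cr_rel_sd = 0.01) {
  if (is.null(sd_d53)) {
    cr_fractionation(cr, d53, mode = "lncr", method = "ols")
  } else {
    cr_fractionation(cr, d53, sx = rep_len(cr_rel_sd, length(cr)),
                     sy = sd_d53, mode = "lncr", method = "york")
  }
}

#' Rayleigh prediction of concentration and isotope composition
#'
#' Closed-system Rayleigh distillation: after a fraction `f` of the initial
#' reservoir remains, `cr = f * cr0` and `d53 = d0 + epsilon * ln(f)`.
#'
#' @param cr0 initial concentration, nmol/kg.
#' @param d0 initial delta-53Cr, permil.
#' @param epsilon enrichment factor, permil.
#' @param f remaining fraction, in (0, 1]. Vectorised.
#' @return `data.frame` with `f`, `cr`, `d53`.
#' @export
#' @examples
#' rayleigh_predict(3.0, 0.9, -0.82, 0.5)
rayleigh_predict <- function(cr0, d0, epsilon, f) {
  if (any(f <= 0 | f > 1)) stop("f must be in (0, 1]")
  data.frame(f = f, cr = f * cr0, d53 = d0 + epsilon * log(f))
}

#' @export
print.cr_fracfit <- function(x, digits = 4, ...) {
  lab <- if (x$mode == "cr3") "delta53Cr ~ [Cr(III)]" else "delta53Cr ~ ln[Cr]"
  cat("Cr isotope fractionation fit (", lab, ", ",
      toupper(x$method), ", n = ", x$n, ")\n", sep = "")
  cat(sprintf("  slope     %+.*f  (95%% CI %+.*f, %+.*f) permil per unit\n",
              digits, x$slope, digits, x$ci95_slope[1], digits, x$ci95_slope[2]))
  cat(sprintf("  intercept %+.*f  (95%% CI %+.*f, %+.*f) permil\n",
              digits, x$intercept, digits, x$ci95_intercept[1],
              digits, x$ci95_intercept[2]))
  cat(sprintf("  r2 = %.3f\n", x$r2))
  if (x$mode == "cr3")
    cat(sprintf("  Delta53Cr = slope x %.2f nmol/kg = %+.*f permil (95%% CI %+.*f, %+.*f)\n",
                x$cr6nr_const, digits, x$delta_cap,
                digits, x$delta_cap_ci[1], digits, x$delta_cap_ci[2]))
  else
    cat(sprintf("  epsilon = %+.*f permil (95%% CI %+.*f, %+.*f)\n",
                digits, x$epsilon, digits, x$epsilon_ci[1], digits, x$epsilon_ci[2]))
  invisible(x)
}

#' @export
summary.cr_fracfit <- function(object, ...) {
  s <- object[c("slope", "intercept", "se_slope", "se_intercept",
                "ci95_slope", "ci95_intercept", "r2", "n", "method", "mode")]
  s$residual_sd <- stats::sd(object$residuals) * sqrt((object$n - 1) / object$df.residual)
  if (object$mode == "cr3") {
    s$delta_vi_nr <- object$delta_vi_nr
    s$delta_cap <- object$delta_cap
    s$delta_cap_ci <- object$delta_cap_ci
  } else {
    s$epsilon <- object$epsilon
    s$epsilon_ci <- object$epsilon_ci
  }
  class(s) <- "summary.cr_fracfit"
  s
}

#' @export
print.summary.cr_fracfit <- function(x, ...) {
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' @export
coef.cr_fracfit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
confint.cr_fracfit <- function(object, parm, level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, df = object$df.residual)
  m <- rbind(intercept = object$intercept + c(-1, 1) * tq * object$se_intercept,
             slope = object$slope + c(-1, 1) * tq * object$se_slope)
  colnames(m) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
predict.cr_fracfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else {
    v <- if (is.list(newdata)) newdata[[1L]] else newdata
    if (object$mode == "lncr") log(v) else v
  }
  object$intercept + object$slope * x
}

#' @export
residuals.cr_fracfit <- function(object, ...) object$residuals

#' @export
plot.cr_fracfit <- function(x, ...) {
  xlab <- if (x$mode == "cr3") "[Cr(III)] (nmol/kg)" else "ln [Cr]"
  graphics::plot(x$x, x$y, xlab = xlab, ylab = expression(delta^53 * Cr ~ "(permil)"),
                 pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = "firebrick", lwd = 2)
  lab <- if (x$mode == "cr3")
    sprintf("Delta53Cr = %.2f permil, r2 = %.2f", x$delta_cap, x$r2)
  else sprintf("epsilon = %.2f permil, r2 = %.2f", x$epsilon, x$r2)
  graphics::mtext(lab, side = 3, line = 0.2, cex = 0.9)
  invisible(x)
}
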