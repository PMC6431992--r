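#' Fit a power law by linear regression in log-log space
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`; the slope is the
#' scaling exponent (the alpha of tau ~ N^alpha, the beta of tau ~
#' kappa^beta, or the slope of tau versus R or E in log-log scale). The fit
#' is unweighted by default, matching a plain linear fit of log-log data;
#' supplying `y_se` with `weighted = TRUE` uses inverse-variance weights on
#' the log scale.
#'
#' @param x,y positive numeric vectors of equal length >= 3.
#' @param y_se optional standard errors of `y` (linear scale).
#' @param weighted use `y_se` to weight the regression.
#' @return A `power_law_fit`: list with `exponent`, `intercept` (log10),
#'   `exponent_se`, `r_squared`, `n_points` and the underlying `lm` fit.
#' @examples
#' fit_power_law(c(10, 20, 40), c(100, 400, 1600))$exponent  # exactly 2
#' @export
fit_power_law <- function(x, y, y_se = NULL, weighted = FALSE) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 points for a power-law fit")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stop("power-law fit requires strictly positive finite x and y")
  lx <- log10(x)
  ly <- log10(y)
  w <- NULL
  if (weighted) {
    if (is.null(y_se)) stop("weighted fit requires 'y_se'")
    se_log <- y_se / (y * log(10))
    w <- 1 / se_log^2
  }
  fit <- if (is.null(w)) lm(ly ~ lx) else lm(ly ~ lx, weights = w)
  sm <- suppressWarnings(summary(fit))   # exact data trips lm's perfect-fit warning
  structure(
    list(exponent = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         exponent_se = unname(sm$coefficients[2, 2]),
         r_squared = sm$r.squared,
         n_points = length(x),
         lm = fit),
    class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power-law fit over %d points: y ~ x^%.4g\n",
              x$n_points, x$exponent))
  cat(sprintf("  exponent %.4g +/- %.3g, intercept (log10) %.4g, R^2 = %.4f\n",
              x$exponent, x$exponent_se, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(intercept = object$intercept, exponent = object$exponent)
}

#' @export
predict.power_law_fit <- function(object, newx, ...) {
  10^object$intercept * newx^object$exponent
}

#' Specify a one-parameter sweep
#'
#' Declares the varying parameter, its grid, the fixed parameters, the
#' per-point ensemble size and the seed origin; [run_sweep()] executes it.
#'
#' @param vary name of the swept `sim_params` field (one of `"r_sep"`,
#'   `"e_field"`, `"kappa"`, `"n_bonds"`).
#' @param grid strictly increasing numeric grid of parameter values.
#' @param params fixed parameters (a [sim_params] object).
#' @param n_samples ensemble size per grid point.
#' @param base_seed seed origin; grid point i uses per-sample seeds
#'   starting at `base_seed + (i - 1) * n_samples`, so no seed is reused
#'   across points.
#' @param fit_range optional `c(lo, hi)` sub-range of the grid over which
#'   the power-law fit is performed (at least 3 grid points must fall in
#'   it).
#' @return A `sweep_spec` object.
#' @export
sweep_spec <- function(vary, grid, params = sim_params(),
                       n_samples = 100, base_seed = params$base_seed,
                       fit_range = NULL) {
  vary <- match.arg(vary, c("r_sep", "e_field", "kappa", "n_bonds"))
  if (length(grid) < 2 || any(diff(grid) <= 0))
    stop("'grid' must be strictly increasing with at least 2 points")
  if (!is.null(fit_range)) {
    if (length(fit_range) != 2 || fit_range[1] >= fit_range[2])
      stop("'fit_range' must be c(lo, hi) with lo < hi")
    if (sum(grid >= fit_range[1] & grid <= fit_range[2]) < 3)
      stop("'fit_range' must contain at least 3 grid points")
  }
  structure(list(vary = vary, grid = grid, params = params,
                 n_samples = n_samples, base_seed = base_seed,
                 fit_range = fit_range),
            class = "sweep_spec")
}

#' Execute a parameter sweep and fit the scaling exponent
#'
#' Runs one translocation ensemble per grid point with deterministic seeds
#' and fits a power law of mean tau against the swept parameter over the
#' configured sub-range. The `engine` argument exists so the sweep plumbing
#' can be exercised with a deterministic stub in tests; by default it is
#' [run_ensemble()].
#'
#' @param spec a [sweep_spec()].
#' @param engine function `(params, n_samples, base_seed)` returning an
#'   object with `tau_mean` and `tau_se` components.
#' @param progress print a line per grid point.
#' @return A `tau_sweep`: list with `spec`, `table` (data.frame of value,
#'   tau_mean, tau_se, n_failed) and `fit` (a `power_law_fit` over the fit
#'   range, or `NULL`).
#' @export
run_sweep <- function(spec, engine = run_ensemble, progress = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  rows <- vector("list", length(spec$grid))
  for (i in seq_along(spec$grid)) {
    p <- spec$params
    p[[spec$vary]] <- spec$grid[i]
    p <- validate_params(unclass(p))
    seed_i <- spec$base_seed + (i - 1) * spec$n_samples
    ens <- engine(p, spec$n_samples, seed_i)
    rows[[i]] <- data.frame(
      value = spec$grid[i],
      tau_mean = ens$tau_mean,
      tau_se = if (!is.null(ens$tau_se)) ens$tau_se else NA_real_,
      n_failed = if (!is.null(ens$n_failed)) ens$n_failed else 0L)
    if (progress)
      message(spec$vary, " = ", spec$grid[i], "  tau = ",
              signif(ens$tau_mean, 5))
  }
  tab <- do.call(rbind, rows)
  fit <- NULL
  if (!is.null(spec$fit_range)) {
    sel <- tab$value >= spec$fit_range[1] & tab$value <= spec$fit_range[2]
    fit <- fit_power_law(tab$value[sel], tab$tau_mean[sel])
  }
  structure(list(spec = spec, table = tab, fit = fit), class = "tau_sweep")
}

#' @export
print.tau_sweep <- function(x, ...) {
  cat(sprintf("Sweep of %s over [%g, %g] (%d points, %d samples each)\n",
              x$spec$vary, min(x$spec$grid), max(x$spec$grid),
              length(x$spec$grid), x$spec$n_samples))
  print(x$table, row.names = FALSE)
  if (!is.null(x$fit)) {
    cat(sprintf("log-log fit over [%g, %g]: exponent %.4g +/- %.3g\n",
                x$spec$fit_range[1], x$spec$fit_range[2],
                x$fit$exponent, x$fit$exponent_se))
  }
  invisible(x)
}

#' @export
plot.tau_sweep <- function(x, ...) {
  tab <- x$table
  plot(tab$value, tab$tau_mean, log = "xy", xlab = x$spec$vary,
       ylab = "mean tau [MCS]", pch = 19, ...)
  if (!all(is.na(tab$tau_se)))
    arrows(tab$value, tab$tau_mean - tab$tau_se,
           tab$value, tab$tau_mean + tab$tau_se,
           angle = 90, code = 3, length = 0.03)
  if (!is.null(x$fit)) {
    xx <- seq(x$spec$fit_range[1], x$spec$fit_range[2], length.out = 50)
    lines(xx, predict(x$fit, xx), col = "red3")
  }
  invisible(x)
}
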