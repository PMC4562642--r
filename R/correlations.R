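#' Growth-rate dose-response correlation
#'
#' A `growth_correlation` maps an inhibitory-factor concentration (pg/mL) to a
#' specific growth rate (fraction/day). Two functional forms are supported:
#' an exponential `a * exp(b * C)` (used for phenotypes whose growth is
#' monotonically suppressed by the factor, `b < 0`) and an interpolating
#' spline through fitted (concentration, rate) points. Evaluation outside the
#' stated concentration domain clamps to the boundary value, so the response
#' is continuous and bounded on `[0, Inf)`.
#'
#' Rates are stored internally as fractions/day; the calibration layer
#' converts from the %/day convention used in reporting.
#'
#' @param kind `"exponential"` or `"spline"`.
#' @param a,b Exponential amplitude (fraction/day) and exponent (mL/pg).
#' @param knots_conc,knots_rate Spline knots: concentrations (pg/mL, strictly
#'   increasing) and rates (fraction/day).
#' @param domain Concentration interval `c(C_min, C_max)` over which the fit
#'   is trusted; evaluation clamps outside it. Defaults to the knot range for
#'   splines and `c(0, Inf)` for exponentials.
#' @return An object of class `growth_correlation`.
#' @examples
#' gc <- growth_correlation("exponential", a = 0.4, b = -0.01)
#' evaluate_growth_rate(gc, 100)  # 0.4 * exp(-1)
#' @export
growth_correlation <- function(kind = c("exponential", "spline"),
                               a = NULL, b = NULL,
                               knots_conc = NULL, knots_rate = NULL,
                               domain = NULL) {
  kind <- match.arg(kind)
  if (kind == "exponential") {
    if (is.null(a) || is.null(b) || !is.finite(a) || !is.finite(b))
      stop("exponential growth correlation requires finite `a` and `b`",
           call. = FALSE)
    if (is.null(domain)) domain <- c(0, Inf)
    obj <- list(kind = kind, a = as.numeric(a), b = as.numeric(b),
                domain = as.numeric(domain))
  } else {
    if (is.null(knots_conc) || is.null(knots_rate) ||
        length(knots_conc) != length(knots_rate) || length(knots_conc) < 2)
      stop("spline growth correlation requires >= 2 matched knots",
           call. = FALSE)
    if (any(diff(knots_conc) <= 0))
      stop("spline knot concentrations must be strictly increasing",
           call. = FALSE)
    if (is.null(domain)) domain <- range(knots_conc)
    obj <- list(kind = kind,
                knots_conc = as.numeric(knots_conc),
                knots_rate = as.numeric(knots_rate),
                domain = as.numeric(domain))
  }
  if (length(obj$domain) != 2 || obj$domain[1] >= obj$domain[2])
    stop("domain must be an increasing interval", call. = FALSE)
  structure(obj, class = "growth_correlation")
}

# Interpolant builder: cubic through the points when there are enough of
# them, piecewise linear otherwise.  Input is clamped to the knot range by
# the caller.
.spline_fun <- function(x, y) {
  if (length(x) >= 4) stats::splinefun(x, y, method = "natural")
  else stats::approxfun(x, y, rule = 2)
}

#' Evaluate a growth correlation at given concentrations
#'
#' @param corr A [growth_correlation()].
#' @param C Concentration(s), pg/mL, `>= 0`. Vectorised.
#' @return Growth rate(s), fraction/day.
#' @export
evaluate_growth_rate <- function(corr, C) {
  stopifnot(inherits(corr, "growth_correlation"))
  if (any(!is.finite(C)) || any(C < 0))
    stop("concentration must be finite and >= 0", call. = FALSE)
  Cc <- pmin(pmax(C, corr$domain[1]), corr$domain[2])
  if (corr$kind == "exponential") {
    corr$a * exp(corr$b * Cc)
  } else {
    Cc <- pmin(pmax(Cc, min(corr$knots_conc)), max(corr$knots_conc))
    .spline_fun(corr$knots_conc, corr$knots_rate)(Cc)
  }
}

#' @export
print.growth_correlation <- function(x, ...) {
  if (x$kind == "exponential") {
    cat(sprintf("growth_correlation: %.4g * exp(%.4g * C) /day, domain [%g, %g] pg/mL\n",
                x$a, x$b, x$domain[1], x$domain[2]))
  } else {
    cat(sprintf("growth_correlation: spline through %d knots on [%g, %g] pg/mL\n",
                length(x$knots_conc), min(x$knots_conc), max(x$knots_conc)))
  }
  invisible(x)
}

#' Secretion-rate correlation
#'
#' Maps the expression-weighted ("adjusted") cell number to a net factor
#' secretion rate in pg/day. The reference form is a single per-adjusted-cell
#' rate (`constant_per_cell`, pg/cell/day); a spline through
#' (adjusted cells, pg/day) points is also supported, with clamped
#' extrapolation beyond the fitted range.
#'
#' @param kind `"constant_per_cell"` or `"spline"`.
#' @param s Per-adjusted-cell secretion rate (pg/cell/day), `>= 0`.
#' @param knots_cells,knots_rate Spline knots: adjusted cell numbers
#'   (strictly increasing) and net secretion rates (pg/day, `>= 0`).
#' @return An object of class `secretion_correlation`.
#' @export
secretion_correlation <- function(kind = c("constant_per_cell", "spline"),
                                  s = NULL,
                                  knots_cells = NULL, knots_rate = NULL) {
  kind <- match.arg(kind)
  if (kind == "constant_per_cell") {
    if (is.null(s) || !is.finite(s) || s < 0)
      stop("constant_per_cell secretion requires finite `s` >= 0", call. = FALSE)
    obj <- list(kind = kind, s = as.numeric(s))
  } else {
    if (is.null(knots_cells) || is.null(knots_rate) ||
        length(knots_cells) != length(knots_rate) || length(knots_cells) < 2)
      stop("spline secretion correlation requires >= 2 matched knots",
           call. = FALSE)
    if (any(diff(knots_cells) <= 0))
      stop("spline knot cell numbers must be strictly increasing", call. = FALSE)
    if (any(knots_rate < 0))
      stop("net secretion rates must be >= 0", call. = FALSE)
    obj <- list(kind = kind,
                knots_cells = as.numeric(knots_cells),
                knots_rate = as.numeric(knots_rate))
  }
  structure(obj, class = "secretion_correlation")
}

#' Net secretion rate at an adjusted cell number
#'
#' @param adjusted Adjusted (expression-weighted) cell number, `>= 0`.
#'   Vectorised.
#' @param secretion A [secretion_correlation()].
#' @return Net secretion rate(s), pg/day.
#' @export
net_secretion_rate <- function(adjusted, secretion) {
  stopifnot(inherits(secretion, "secretion_correlation"))
  if (any(!is.finite(adjusted)) || any(adjusted < 0))
    stop("adjusted cell number must be finite and >= 0", call. = FALSE)
  if (secretion$kind == "constant_per_cell") {
    secretion$s * adjusted
  } else {
    a <- pmin(pmax(adjusted, min(secretion$knots_cells)),
              max(secretion$knots_cells))
    pmax(.spline_fun(secretion$knots_cells, secretion$knots_rate)(a), 0)
  }
}

#' @export
print.secretion_correlation <- function(x, ...) {
  if (x$kind == "constant_per_cell") {
    cat(sprintf("secretion_correlation: %.4g pg per adjusted cell per day\n", x$s))
  } else {
    cat(sprintf("secretion_correlation: spline through %d knots\n",
                length(x$knots_cells)))
  }
  invisible(x)
}
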