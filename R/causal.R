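#' True causal dose-response functions for the generator
#'
#' Tagged descriptions of the causal effect of circulating 25(OH)D (nmol/L)
#' on grip strength (kg) used by [simulate_cohort()] as ground truth:
#'
#' * `causal_null()`: no effect.
#' * `causal_linear(slope)`: effect `slope * x` (kg per nmol/L).
#' * `causal_plateau(slope, knot)`: effect `slope * min(x, knot)` - linear gain
#'   below the knot, flat above it. With the knot at 50 nmol/L the true mean
#'   difference between 75 and 50 nmol/L is exactly 0 and between 25 and
#'   50 nmol/L is `-25 * slope`.
#' * `causal_fp(power, coef)`: a single fractional-polynomial term,
#'   `coef * x^power` (`coef * ln x` when `power == 0`).
#'
#' @param slope Effect in kg per nmol/L (below the knot, for the plateau).
#' @param knot Plateau knot in nmol/L.
#' @param power A fractional-polynomial power (0 means natural log).
#' @param coef Coefficient of the FP term.
#' @return An object of class `causal_fn`.
#' @examples
#' causal_effect(causal_plateau(0.04, 50), c(25, 50, 75))
#' @export
causal_null <- function() {
  structure(list(type = "null"), class = "causal_fn")
}

#' @rdname causal_null
#' @export
causal_linear <- function(slope) {
  stopifnot(is.numeric(slope), length(slope) == 1, is.finite(slope))
  structure(list(type = "linear", slope = slope), class = "causal_fn")
}

#' @rdname causal_null
#' @export
causal_plateau <- function(slope, knot = 50) {
  stopifnot(is.finite(slope), is.finite(knot), knot > 0)
  structure(list(type = "plateau", slope = slope, knot = knot),
            class = "causal_fn")
}

#' @rdname causal_null
#' @export
causal_fp <- function(power, coef) {
  stopifnot(is.finite(power), is.finite(coef))
  structure(list(type = "fp", power = power, coef = coef),
            class = "causal_fn")
}

#' Evaluate a causal function
#'
#' @param fn A `causal_fn` object.
#' @param x Exposure values in nmol/L (positive).
#' @return The causal contribution to mean grip strength, in kg.
#' @export
causal_effect <- function(fn, x) {
  stopifnot(inherits(fn, "causal_fn"))
  switch(fn$type,
    null = rep(0, length(x)),
    linear = fn$slope * x,
    plateau = fn$slope * pmin(x, fn$knot),
    fp = if (fn$power == 0) fn$coef * log(x) else fn$coef * x^fn$power,
    abort("unknown causal function type")
  )
}

#' True outcome difference versus a reference exposure
#'
#' Ground truth for curve-recovery tests: the causal mean difference in grip
#' strength between exposure `x` and `reference` nmol/L.
#'
#' @inheritParams causal_effect
#' @param reference Reference exposure (nmol/L), default 50.
#' @return Numeric vector of kg differences.
#' @export
true_difference <- function(fn, x, reference = 50) {
  causal_effect(fn, x) - causal_effect(fn, reference)
}

#' @export
print.causal_fn <- function(x, ...) {
  desc <- switch(x$type,
    null = "null (no causal effect)",
    linear = sprintf("linear: %.4g kg per nmol/L", x$slope),
    plateau = sprintf("plateau: %.4g kg per nmol/L below %g nmol/L, flat above",
                      x$slope, x$knot),
    fp = sprintf("fractional polynomial term: %.4g * %s",
                 x$coef, if (x$power == 0) "ln(x)" else sprintf("x^%g", x$power))
  )
  cat("<causal_fn> ", desc, "\n", sep = "")
  invisible(x)
}
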