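#' Parametric hazard forms
#'
#' A cause- and group-specific hazard used by the simulation engine and
#' the closed-form estimands.  Three shapes are supported, covering
#' exponential and Weibull event-time distributions:
#'
#' * `"constant"`: rate `a`, cumulative hazard `a t` (exponential);
#' * `"linear"`: rate `a t`, cumulative hazard `a t^2 / 2` (Weibull,
#'   shape 2);
#' * `"power"`: rate `a t^b` with `b > -1`, cumulative hazard
#'   `a t^(b+1) / (b+1)` (Weibull).
#'
#' @param shape One of `"constant"`, `"linear"`, `"power"`.
#' @param a Positive scale parameter.
#' @param b Power exponent, `> -1`; only used for `shape = "power"`.
#' @return An object of class `hazard_form`.
#' @examples
#' hazard_form("power", 0.192, -0.2)
#' @export
hazard_form <- function(shape = c("constant", "linear", "power"), a, b = NULL) {
  shape <- match.arg(shape)
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' must be a positive number")
  if (shape == "power") {
    if (is.null(b) || !is.finite(b) || b <= -1)
      stop("'b' must be a number > -1 for the power shape")
  } else b <- NULL
  structure(list(shape = shape, a = a, b = b), class = "hazard_form")
}

#' @export
print.hazard_form <- function(x, ...) {
  cat(switch(x$shape,
    constant = sprintf("<hazard> %g\n", x$a),
    linear = sprintf("<hazard> %g * t\n", x$a),
    power = sprintf("<hazard> %g * t^%g\n", x$a, x$b)))
  invisible(x)
}

#' Hazard rate, cumulative hazard, and its inverse
#'
#' `hazard_rate()` evaluates the hazard `lambda(t)`, `cum_hazard()` the
#' cumulative hazard `Lambda(t)`, and `inv_cum_hazard()` the exact inverse
#' `Lambda^{-1}(y)`; all are closed-form per shape, no root finding is
#' involved.
#'
#' @param form A [hazard_form()] object.
#' @param t Time(s), `>= 0`.
#' @param y Cumulative-hazard value(s), `>= 0`.
#' @return Numeric vector of the same length as `t` (or `y`).
#' @examples
#' f <- hazard_form("linear", 0.1)
#' inv_cum_hazard(f, cum_hazard(f, 2))  # 2
#' @export
cum_hazard <- function(form, t) {
  stopifnot(inherits(form, "hazard_form"))
  if (any(t < 0)) stop("'t' must be non-negative")
  switch(form$shape,
    constant = form$a * t,
    linear = form$a * t^2 / 2,
    power = form$a * t^(form$b + 1) / (form$b + 1))
}

#' @rdname cum_hazard
#' @export
hazard_rate <- function(form, t) {
  stopifnot(inherits(form, "hazard_form"))
  switch(form$shape,
    constant = rep_len(form$a, length(t)),
    linear = form$a * t,
    power = form$a * t^form$b)
}

#' @rdname cum_hazard
#' @export
inv_cum_hazard <- function(form, y) {
  stopifnot(inherits(form, "hazard_form"))
  if (any(y < 0)) stop("'y' must be non-negative")
  switch(form$shape,
    constant = y / form$a,
    linear = sqrt(2 * y / form$a),
    power = ((form$b + 1) * y / form$a)^(1 / (form$b + 1)))
}

#' Scale a hazard form by a proportional effect
#'
#' Multiplies the scale parameter by a hazard ratio, i.e. applies a
#' proportional treatment effect `exp(beta)` to a baseline hazard.
#'
#' @param form A [hazard_form()] object.
#' @param hr Positive hazard ratio.
#' @return A `hazard_form` with `a * hr`.
#' @export
scale_hazard <- function(form, hr) {
  if (hr <= 0) stop("hazard ratio must be positive")
  hazard_form(form$shape, form$a * hr, form$b)
}
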