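#' Relevance weight scheme for a composite endpoint
#'
#' Creates a validated pair of relevance weights for the fatal and the
#' non-fatal component of the composite endpoint.  Each of the three
#' analysis approaches has its own convention:
#'
#' * `"weilachin"`: relative weights acting on the cause-specific log
#'   hazard ratios; both must be strictly positive and sum to 1.
#' * `"rauch"`: weights acting multiplicatively on the cause-specific
#'   hazards; non-negative, not both zero, conventionally 1 for the most
#'   clinically relevant event and at most 1 for the others.
#' * `"bakal"`: weights in `[0, 1]` depleting the individual score; 1 for
#'   a fatal (most relevant) event.
#'
#' @param method One of `"weilachin"`, `"rauch"`, `"bakal"`.
#' @param w_fatal Weight for the fatal event (death).
#' @param w_nonfatal Weight for the non-fatal, possibly recurrent event.
#' @return An object of class `weight_scheme`: a list with elements
#'   `method`, `w_fatal`, `w_nonfatal`.
#' @examples
#' weight_scheme("weilachin", 0.5263, 0.4737)
#' weight_scheme("rauch", 1, 0.5)
#' @export
weight_scheme <- function(method = c("weilachin", "rauch", "bakal"),
                          w_fatal, w_nonfatal) {
  method <- match.arg(method)
  scheme <- structure(
    list(method = method, w_fatal = w_fatal, w_nonfatal = w_nonfatal),
    class = "weight_scheme"
  )
  validate_weights(scheme)
}

#' Validate a weight scheme
#'
#' Checks the method-specific constraints on the relevance weights and
#' returns the scheme unchanged when they hold.
#'
#' @param scheme A [weight_scheme()] object (or a list with the same
#'   fields).
#' @param tol Tolerance for the Wei-Lachin sum-to-one constraint.
#' @return `scheme`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_weights <- function(scheme, tol = 1e-9) {
  w <- c(scheme$w_fatal, scheme$w_nonfatal)
  if (!is.numeric(w) || length(w) != 2L || anyNA(w) || any(!is.finite(w)))
    stop("weights must be finite numbers")
  if (any(w < 0))
    stop("relevance weights must be non-negative")
  switch(scheme$method,
    weilachin = {
      if (any(w <= 0))
        stop("Wei-Lachin weights must be strictly positive")
      if (abs(sum(w) - 1) > tol)
        stop("Wei-Lachin weights must sum to 1 (got ",
             format(sum(w), digits = 12), ")")
    },
    bakal = {
      if (any(w > 1))
        stop("Bakal weights must lie in [0, 1]")
    },
    rauch = {
      if (all(w == 0))
        stop("Rauch weights must not both be zero")
    },
    stop("unknown weighting method: ", scheme$method)
  )
  scheme
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat(sprintf("<weight_scheme %s> w_fatal = %g, w_nonfatal = %g\n",
              x$method, x$w_fatal, x$w_nonfatal))
  invisible(x)
}

stopifnot_scheme <- function(scheme, method) {
  if (!inherits(scheme, "weight_scheme"))
    stop("'scheme' must be a weight_scheme object")
  if (scheme$method != method)
    stop("this analysis requires a '", method, "' weight scheme, got '",
         scheme$method, "'")
  invisible(scheme)
}
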