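#' One-sided test result
#'
#' Container for the one-sided tests of all three approaches.  Every
#' statistic is asymptotically standard normal under its null; the null
#' (control at least as good as intervention) is rejected when the
#' statistic falls at or below `-z_(1-alpha)`.
#'
#' @param statistic Test statistic value.
#' @param alpha One-sided significance level in (0, 1).
#' @param method Label of the originating approach.
#' @return An object of class `test_result` with fields `statistic`,
#'   `p_one_sided` (`pnorm(statistic)`), `alpha`, `reject`, `method`.
#' @export
test_result <- function(statistic, alpha, method = "") {
  stopifnot(is.finite(statistic), alpha > 0, alpha < 1)
  structure(list(statistic = statistic,
                 p_one_sided = stats::pnorm(statistic),
                 alpha = alpha,
                 reject = statistic <= -stats::qnorm(1 - alpha),
                 method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s one-sided test: T = %.4f, p = %.4g, %s at alpha = %g\n",
              x$method, x$statistic, x$p_one_sided,
              if (x$reject) "reject H0" else "do not reject H0", x$alpha))
  invisible(x)
}

#' Effect estimate on the hazard-ratio scale
#'
#' @param point Positive point estimate.
#' @param ci_lower,ci_upper Optional confidence limits.
#' @param level Confidence level of the interval, if present.
#' @param method Label of the originating approach.
#' @return An object of class `effect_estimate`.
#' @export
effect_estimate <- function(point, ci_lower = NA_real_, ci_upper = NA_real_,
                            level = NA_real_, method = "") {
  if (!is.finite(point) || point <= 0)
    stop("effect estimate must be a positive number")
  if (is.finite(ci_lower) && is.finite(ci_upper) && ci_lower > ci_upper)
    stop("lower confidence limit exceeds the upper limit")
  structure(list(point = point, ci_lower = ci_lower, ci_upper = ci_upper,
                 level = level, method = method),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (is.finite(x$ci_lower))
    cat(sprintf("%s weighted hazard ratio: %.4f (%.0f%% CI %.4f to %.4f)\n",
                x$method, x$point, 100 * x$level, x$ci_lower, x$ci_upper))
  else
    cat(sprintf("%s weighted hazard ratio: %.4f\n", x$method, x$point))
  invisible(x)
}
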