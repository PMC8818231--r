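## Wei-Lachin weighted hazard ratio.
##
## Cause-specific stratified Cox models (one per event type, strata =
## event number, the other event type censored within its stratum) give
## log hazard-ratio estimates beta_D, beta_M.  The two models are stacked
## in working-independence fashion: per-subject score residuals,
## aggregated over a subject's rows, provide a sandwich covariance for
## (beta_D, beta_M), including the cross-cause term needed by the
## weighted test.

#' Fit a stratified cause-specific Cox model
#'
#' Maximizes the stratified partial likelihood for the single binary
#' group covariate on the counting-process table, with strata equal to
#' the event number and events of the other cause treated as censorings
#' within their stratum.  Breslow tie handling is used (simulated times
#' are almost surely tie-free; real data may tie).  The fit is flagged as
#' non-converged when the cause has no events, when all its events fall
#' in one group (monotone likelihood), or when the Newton iterations do
#' not converge; downstream Monte-Carlo summaries drop such replicates.
#'
#' @param cp A [to_counting_process()] table.
#' @param cause `"fatal"` or `"nonfatal"`.
#' @return An object of class `strat_cox_fit`: list with `cause`,
#'   `beta` (log hazard ratio), `var_model` (inverse information),
#'   `var_robust` (score-residual sandwich), `information`,
#'   `score_resid` (named per-subject aggregated score residuals),
#'   `n_events`, `n_events_by_group`, `converged`.
#' @export
fit_stratified_cox <- function(cp, cause = c("fatal", "nonfatal")) {
  cause <- match.arg(cause)
  code <- if (cause == "fatal") STATUS_FATAL else STATUS_NONFATAL
  ev <- cp$status == code
  subjects <- sort(unique(as.character(cp$id)))
  by_group <- c(sum(ev & cp$group == 0L), sum(ev & cp$group == 1L))
  out <- list(cause = cause, beta = NA_real_, var_model = NA_real_,
              var_robust = NA_real_, information = NA_real_,
              score_resid = stats::setNames(rep(NA_real_, length(subjects)),
                                            subjects),
              n_events = sum(ev), n_events_by_group = by_group,
              converged = FALSE)
  class(out) <- "strat_cox_fit"
  if (sum(ev) == 0L || any(by_group == 0L))
    return(out)
  df <- data.frame(start = cp$start, stop = cp$stop, event = as.integer(ev),
                   group = cp$group, stratum = cp$stratum)
  bad <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(start, stop, event) ~ group + survival::strata(stratum),
      data = df, ties = "breslow", x = TRUE,
      control = survival::coxph.control(eps = 1e-10, iter.max = 50L)),
    warning = function(w) {
      bad <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[1L])
  var_model <- fit$var[1L, 1L]
  sc <- score_residuals_by_subject(fit, as.character(cp$id))
  out$beta <- beta
  out$var_model <- var_model
  out$information <- 1 / var_model
  out$score_resid <- sc[subjects]
  out$var_robust <- var_model^2 * sum(sc^2)
  out$converged <- !bad && is.finite(beta) && abs(beta) < 15 &&
    is.finite(var_model) && var_model > 0
  out
}

# per-subject aggregated score residuals of a single-covariate coxph fit
score_residuals_by_subject <- function(fit, id) {
  rr <- stats::residuals(fit, type = "score")
  agg <- rowsum(as.numeric(rr), id)
  stats::setNames(agg[, 1L], rownames(agg))[sort(unique(id))]
}

#' @export
print.strat_cox_fit <- function(x, ...) {
  cat(sprintf("Stratified Cox fit (%s): beta = %.4f, HR = %.4f, %d events%s\n",
              x$cause, x$beta, exp(x$beta), x$n_events,
              if (x$converged) "" else " [non-converged]"))
  invisible(x)
}

#' Cross-cause covariance of the two log hazard-ratio estimators
#'
#' Working-independence stacked-model covariance: with per-subject
#' aggregated score residuals `U_i,c` and observed information `I_c` of
#' cause `c`, the covariance of `(beta_D, beta_M)` is estimated as
#' `I_D^-1 (sum_i U_i,D U_i,M) I_M^-1`.
#'
#' @param fit_fatal,fit_nonfatal [fit_stratified_cox()] results sharing
#'   the same subject universe.
#' @return The estimated covariance `sigma_DM` (a number).
#' @export
wl_covariance <- function(fit_fatal, fit_nonfatal) {
  uD <- fit_fatal$score_resid
  uM <- fit_nonfatal$score_resid
  if (!identical(names(uD), names(uM)))
    stop("the two fits do not share the same subjects")
  fit_fatal$var_model * sum(uD * uM) * fit_nonfatal$var_model
}

#' True Wei-Lachin weighted hazard ratio
#'
#' The estimand `exp(w_D log hr_D + w_M log hr_M)` for given constant
#' cause-specific hazard ratios.
#'
#' @param hr_fatal,hr_nonfatal Positive cause-specific hazard ratios.
#' @param scheme A `"weilachin"` [weight_scheme()].
#' @return The weighted hazard ratio.
#' @examples
#' wl_true_theta(0.7, 0.5, weight_scheme("weilachin", 0.5263, 0.4737))
#' @export
wl_true_theta <- function(hr_fatal, hr_nonfatal, scheme) {
  stopifnot_scheme(scheme, "weilachin")
  if (hr_fatal <= 0 || hr_nonfatal <= 0)
    stop("hazard ratios must be positive")
  exp(scheme$w_fatal * log(hr_fatal) + scheme$w_nonfatal * log(hr_nonfatal))
}

wl_variance <- function(fit_fatal, fit_nonfatal, sigma_DM, scheme,
                        variance = c("robust", "model")) {
  variance <- match.arg(variance)
  s2D <- if (variance == "robust") fit_fatal$var_robust else fit_fatal$var_model
  s2M <- if (variance == "robust") fit_nonfatal$var_robust else fit_nonfatal$var_model
  v <- scheme$w_fatal^2 * s2D + 2 * scheme$w_fatal * scheme$w_nonfatal * sigma_DM +
    scheme$w_nonfatal^2 * s2M
  if (!is.finite(v) || v <= 0)
    stop("non-positive variance for the weighted log hazard ratio")
  v
}

#' Wei-Lachin weighted test
#'
#' One-sided multivariate test of the null "weighted hazard ratio >= 1":
#' the statistic is the weighted sum of the cause-specific log hazard
#' ratio estimates divided by the standard error combining both variances
#' and the cross-cause covariance; it is asymptotically standard normal
#' under the null and the null is rejected when it is `<= -z_(1-alpha)`.
#'
#' @param fit_fatal,fit_nonfatal [fit_stratified_cox()] results.
#' @param sigma_DM Cross-cause covariance; computed via
#'   [wl_covariance()] when `NULL`.
#' @param scheme A `"weilachin"` [weight_scheme()].
#' @param alpha One-sided significance level (default 0.025).
#' @param variance `"robust"` (score-residual sandwich, default) or
#'   `"model"` (inverse information) for the cause-specific variances.
#' @return A [test_result()].
#' @export
wl_test <- function(fit_fatal, fit_nonfatal, sigma_DM = NULL, scheme,
                    alpha = 0.025, variance = c("robust", "model")) {
  if (scheme$method != "weilachin")
    stop("wl_test requires a 'weilachin' weight scheme")
  if (is.null(sigma_DM)) sigma_DM <- wl_covariance(fit_fatal, fit_nonfatal)
  num <- scheme$w_fatal * fit_fatal$beta + scheme$w_nonfatal * fit_nonfatal$beta
  v <- wl_variance(fit_fatal, fit_nonfatal, sigma_DM, scheme, variance)
  test_result(num / sqrt(v), alpha, method = "Wei-Lachin")
}

#' Wei-Lachin weighted hazard ratio estimate and confidence interval
#'
#' Point estimate `exp(w_D beta_D + w_M beta_M)` with the
#' `(1 - 2 alpha)` interval obtained by exponentiating the symmetric
#' normal interval on the log scale, using the same combined variance as
#' the test.
#'
#' @inheritParams wl_test
#' @return An [effect_estimate()] with a `(1 - 2 alpha)` interval.
#' @export
wl_estimate_ci <- function(fit_fatal, fit_nonfatal, sigma_DM = NULL, scheme,
                           alpha = 0.025, variance = c("robust", "model")) {
  if (scheme$method != "weilachin")
    stop("wl_estimate_ci requires a 'weilachin' weight scheme")
  if (is.null(sigma_DM)) sigma_DM <- wl_covariance(fit_fatal, fit_nonfatal)
  lp <- scheme$w_fatal * fit_fatal$beta + scheme$w_nonfatal * fit_nonfatal$beta
  se <- sqrt(wl_variance(fit_fatal, fit_nonfatal, sigma_DM, scheme, variance))
  z <- stats::qnorm(1 - alpha)
  effect_estimate(exp(lp), exp(lp - z * se), exp(lp + z * se),
                  level = 1 - 2 * alpha, method = "Wei-Lachin")
}

#' Complete Wei-Lachin analysis of a counting-process table
#'
#' Convenience wrapper: fits both cause-specific stratified Cox models,
#' computes the cross-cause covariance, the one-sided test, and the
#' weighted hazard-ratio estimate with confidence interval.
#'
#' @param cp A [to_counting_process()] table.
#' @inheritParams wl_test
#' @return A list with `fit_fatal`, `fit_nonfatal`, `sigma_DM`, `test`,
#'   `estimate`, `converged`.  When either Cox fit is degenerate the
#'   analysis is flagged `converged = FALSE` and `test`/`estimate` are
#'   `NULL`.
#' @export
weilachin_analysis <- function(cp, scheme, alpha = 0.025,
                               variance = c("robust", "model")) {
  variance <- match.arg(variance)
  fit_D <- fit_stratified_cox(cp, "fatal")
  fit_M <- fit_stratified_cox(cp, "nonfatal")
  if (!fit_D$converged || !fit_M$converged)
    return(list(fit_fatal = fit_D, fit_nonfatal = fit_M, sigma_DM = NA_real_,
                test = NULL, estimate = NULL, converged = FALSE))
  sDM <- wl_covariance(fit_D, fit_M)
  list(fit_fatal = fit_D, fit_nonfatal = fit_M, sigma_DM = sDM,
       test = wl_test(fit_D, fit_M, sDM, scheme, alpha, variance),
       estimate = wl_estimate_ci(fit_D, fit_M, sDM, scheme, alpha, variance),
       converged = TRUE)
}
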