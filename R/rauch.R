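## Weighted all-cause hazard ratio.
##
## The estimand is the ratio of relevance-weighted sums of cause-specific
## hazards, averaged over strata; the non-parametric estimator replaces
## hazards by stratified cause- and group-specific Nelson-Aalen cumulative
## hazards at the evaluation time.  The companion test is a stratified
## weight-based log-rank statistic in which the relevance weights act
## multiplicatively on the event counts.

# number at risk at each of `times` for rows with interval (start, stop]
risk_at <- function(start, stop, times) {
  findInterval(times, sort(start), left.open = TRUE) -
    findInterval(times, sort(stop), left.open = TRUE)
}

# sums of `vals` grouped by integer index 1..k
indexed_sum <- function(vals, idx, k) {
  out <- numeric(k)
  if (length(idx)) {
    agg <- rowsum(vals, idx)
    out[as.integer(rownames(agg))] <- agg[, 1L]
  }
  out
}

#' Stratified cause- and group-specific Nelson-Aalen estimator
#'
#' Step-function estimate of the cumulative hazard in one
#' (cause, group, stratum) cell of the counting process: jumps of
#' `d / Y` at each event time of the cause, where `Y` counts rows of the
#' cell at risk (`start < t <= stop`).
#'
#' @param cp A [to_counting_process()] table.
#' @param cause `"fatal"` or `"nonfatal"`.
#' @param group 1 (intervention) or 0 (control).
#' @param stratum Stratum index (event number), `>= 1`.
#' @return An object of class `nelson_aalen`: list with `time` (jump
#'   times), `cumhaz` (cumulative values), `n_risk`, `n_event`; attribute
#'   `empty` flags a cell without rows.  Evaluate with [na_at()].
#' @export
nelson_aalen <- function(cp, cause = c("fatal", "nonfatal"), group, stratum) {
  cause <- match.arg(cause)
  code <- if (cause == "fatal") STATUS_FATAL else STATUS_NONFATAL
  sel <- cp$group == group & cp$stratum == stratum
  start <- cp$start[sel]; stop <- cp$stop[sel]; status <- cp$status[sel]
  times <- sort(unique(stop[status == code]))
  out <- structure(
    list(time = times, cumhaz = numeric(length(times)),
         n_risk = numeric(length(times)), n_event = numeric(length(times))),
    class = "nelson_aalen", empty = !any(sel))
  if (length(times) == 0L) return(out)
  d <- indexed_sum(rep(1, sum(status == code)),
                   match(stop[status == code], times), length(times))
  y <- risk_at(start, stop, times)
  out$n_risk <- y
  out$n_event <- d
  out$cumhaz <- cumsum(d / y)
  out
}

#' @rdname nelson_aalen
#' @param x A `nelson_aalen` object.
#' @param t Evaluation time(s); right-continuous evaluation, 0 before the
#'   first jump.
#' @export
na_at <- function(x, t) {
  c(0, x$cumhaz)[findInterval(t, x$time) + 1L]
}

#' @export
print.nelson_aalen <- function(x, ...) {
  cat(sprintf("Nelson-Aalen estimate: %d jump times, Lambda(max) = %.4f\n",
              length(x$time), if (length(x$cumhaz)) max(x$cumhaz) else 0))
  invisible(x)
}

#' True weighted all-cause hazard ratio of a scenario
#'
#' Evaluates the estimand at time `t` from the scenario's parametric
#' hazards: the ratio of the weighted sums of the cause-specific hazards
#' of the intervention and the control group.  Since the scenarios carry
#' no strata-specific effects, the average over strata equals the
#' single-stratum value.
#'
#' @param spec A [scenario_spec()].
#' @param scheme A `"rauch"` [weight_scheme()].
#' @param t Evaluation time in years (default: the scenario horizon, i.e.
#'   the end of study).
#' @return The weighted all-cause hazard ratio at `t`.
#' @examples
#' rauch_true_theta(get_scenario("2a"), weight_scheme("rauch", 1, 0.9))
#' @export
rauch_true_theta <- function(spec, scheme, t = spec$horizon) {
  stopifnot_scheme(scheme, "rauch")
  if (t <= 0) stop("'t' must be positive")
  num <- scheme$w_fatal * hazard_rate(spec$hazards$I_fatal, t) +
    scheme$w_nonfatal * hazard_rate(spec$hazards$I_nonfatal, t)
  den <- scheme$w_fatal * hazard_rate(spec$hazards$C_fatal, t) +
    scheme$w_nonfatal * hazard_rate(spec$hazards$C_nonfatal, t)
  if (den <= 0) stop("weighted control hazard is zero at t = ", t)
  num / den
}

# weighted cumulative-hazard totals at time t for one (group, stratum)
# cell: w_D * Lambda_D(t) + w_M * Lambda_M(t), summed event jumps d/Y
cell_weighted_cumhaz <- function(start, stop, status, t, w_fatal, w_nonfatal) {
  ev <- status != STATUS_CENSORED & stop <= t
  if (!any(ev)) return(0)
  times <- sort(unique(stop[ev]))
  y <- risk_at(start, stop, times)
  idx <- match(stop[ev], times)
  w <- ifelse(status[ev] == STATUS_FATAL, w_fatal, w_nonfatal)
  sum(indexed_sum(w, idx, length(times)) / y)
}

# group-wise weighted cumulative hazard, pooled over strata: the risk
# set at time s counts every subject still under observation (all
# subjects enter at 0, leave at their last stop), and each event of
# cause c contributes w_c / Y(s).  Under equal baseline hazards across
# strata this is the Nelson-Aalen analogue of the Breslow estimator of
# the stratified model, using every recurrence.
pooled_weighted_cumhaz <- function(stop, status, end_by_subject, t,
                                   w_fatal, w_nonfatal) {
  ev <- status != STATUS_CENSORED & stop <= t
  if (!any(ev)) return(0)
  times <- sort(unique(stop[ev]))
  y <- length(end_by_subject) -
    findInterval(times, sort(end_by_subject), left.open = TRUE)
  idx <- match(stop[ev], times)
  w <- ifelse(status[ev] == STATUS_FATAL, w_fatal, w_nonfatal)
  sum(indexed_sum(w, idx, length(times)) / y)
}

#' Non-parametric weighted all-cause hazard ratio estimate
#'
#' Replaces the hazards in the estimand by Nelson-Aalen cumulative
#' hazards at time `t` and forms the ratio of the weighted
#' intervention and control totals.  Two aggregations over strata are
#' available; they estimate the same quantity under the equal
#' baseline-hazards assumption:
#'
#' * `"pooled"` (default): cause-specific cumulative hazards computed on
#'   the pooled risk set -- a subject is at risk while under observation
#'   and every recurrence contributes -- which extends the
#'   time-to-first-event estimator to recurrent events and uses all
#'   events with stable risk sets;
#' * `"strata"`: the average over strata of the per-stratum weighted
#'   Nelson-Aalen ratios; strata enter only when both group totals are
#'   strictly positive (degenerate 0/0 cells late in follow-up are
#'   excluded and the averaging constant is the number of included
#'   strata).  Per-stratum risk sets become very small for higher event
#'   numbers, making this variant considerably more variable.
#'
#' With all weights equal and a single stratum both reduce exactly to
#' the all-cause Nelson-Aalen ratio.
#'
#' @param cp A [to_counting_process()] table.
#' @param scheme A `"rauch"` [weight_scheme()].
#' @param t Evaluation time in years (default: the table's horizon).
#' @param combine `"pooled"` or `"strata"`, see above.
#' @return An [effect_estimate()] (no interval; see
#'   [rauch_bootstrap_ci()]).
#' @export
rauch_estimate <- function(cp, scheme, t = attr(cp, "horizon"),
                           combine = c("pooled", "strata")) {
  stopifnot_scheme(scheme, "rauch")
  combine <- match.arg(combine)
  if (is.null(t) || is.na(t))
    stop("no evaluation time: supply 't' or a table with a horizon")
  if (!any(cp$status != STATUS_CENSORED))
    stop("no events in the counting process")
  if (combine == "pooled") {
    val <- numeric(2)
    for (g in c(1L, 0L)) {
      sel <- cp$group == g
      ends <- vapply(split(cp$stop[sel], as.character(cp$id[sel])), max,
                     numeric(1), USE.NAMES = FALSE)
      val[2L - g] <- pooled_weighted_cumhaz(
        cp$stop[sel], cp$status[sel], ends, t,
        scheme$w_fatal, scheme$w_nonfatal)
    }
    if (val[1L] <= 0 || val[2L] <= 0)
      stop("no weighted events within the evaluation time in both groups")
    return(effect_estimate(val[1L] / val[2L], method = "Rauch"))
  }
  ratios <- numeric(0)
  for (j in sort(unique(cp$stratum))) {
    sj <- cp$stratum == j
    num <- den <- 0
    for (g in c(1L, 0L)) {
      sel <- sj & cp$group == g
      v <- cell_weighted_cumhaz(cp$start[sel], cp$stop[sel], cp$status[sel],
                                t, scheme$w_fatal, scheme$w_nonfatal)
      if (g == 1L) num <- v else den <- v
    }
    if (num > 0 && den > 0) ratios[length(ratios) + 1L] <- num / den
  }
  if (length(ratios) == 0L)
    stop("no stratum with positive weighted totals in both groups")
  effect_estimate(mean(ratios), method = "Rauch")
}

#' Stratified weight-based log-rank test
#'
#' One-sided test of the null "weighted all-cause hazard ratio >= 1".
#' Within each stratum, at each distinct event time the relevance weights
#' act multiplicatively on the cause-specific event counts: with
#' type-weighted counts `wO = sum_c w_c dN_c`, the numerator accumulates
#' `wO_I - (Y_I / Y) wO` and the variance
#' `(Y_I Y_C / Y^2) ((Y - dN) / (Y - 1)) sum_c w_c^2 dN_c`, where `Y`
#' are numbers at risk and `dN` the unweighted event count (simultaneous
#' events are processed jointly).  Times with `Y <= 1` are skipped.  With
#' all weights 1 the statistic is the classical stratified all-cause
#' log-rank statistic; it is asymptotically standard normal under the
#' null and rejects when `<= -z_(1-alpha)`.
#'
#' @param cp A [to_counting_process()] table.
#' @param scheme A `"rauch"` [weight_scheme()].
#' @param alpha One-sided significance level (default 0.025).
#' @return A [test_result()].
#' @export
rauch_test <- function(cp, scheme, alpha = 0.025) {
  stopifnot_scheme(scheme, "rauch")
  num <- var <- 0
  for (j in sort(unique(cp$stratum))) {
    sj <- which(cp$stratum == j)
    start <- cp$start[sj]; stop <- cp$stop[sj]
    status <- cp$status[sj]; grp <- cp$group[sj]
    ev <- status != STATUS_CENSORED
    if (!any(ev)) next
    times <- sort(unique(stop[ev]))
    k <- length(times)
    yI <- risk_at(start[grp == 1L], stop[grp == 1L], times)
    yC <- risk_at(start[grp == 0L], stop[grp == 0L], times)
    y <- yI + yC
    idx <- match(stop[ev], times)
    w <- ifelse(status[ev] == STATUS_FATAL, scheme$w_fatal, scheme$w_nonfatal)
    wO <- indexed_sum(w, idx, k)
    wOI <- indexed_sum(w * (grp[ev] == 1L), idx, k)
    w2O <- indexed_sum(w^2, idx, k)
    dN <- indexed_sum(rep(1, sum(ev)), idx, k)
    use <- y > 1
    num <- num + sum((wOI - yI / y * wO)[use])
    var <- var +
      sum((yI * yC / y^2 * (y - dN) / (y - 1) * w2O)[use])
  }
  if (var <= 0)
    stop("zero variance: no usable event times for the weighted log-rank test")
  test_result(num / sqrt(var), alpha, method = "Rauch")
}

#' Bootstrap confidence interval for the weighted all-cause hazard ratio
#'
#' No closed-form variance exists for the non-parametric estimator, so a
#' percentile interval is obtained from subject-level resampling:
#' subjects are drawn with replacement within treatment group (entire
#' histories, preserving within-subject dependence and the group
#' allocation), and the estimator is recomputed on each resample.
#'
#' @param histories An [event_histories()] object.
#' @param scheme A `"rauch"` [weight_scheme()].
#' @param t Evaluation time (default: the horizon of `histories`).
#' @param alpha One-sided level; the interval has level `1 - 2 alpha`.
#' @param B Number of bootstrap resamples, at least 100.
#' @param combine Aggregation passed to [rauch_estimate()].
#' @return An [effect_estimate()] whose point comes from the original
#'   data and whose interval is the percentile `(alpha, 1 - alpha)`
#'   interval.  Errors when more than 20% of resamples fail estimation.
#' @export
rauch_bootstrap_ci <- function(histories, scheme, t = attr(histories, "horizon"),
                               alpha = 0.025, B = 1000L,
                               combine = c("pooled", "strata")) {
  stopifnot_scheme(scheme, "rauch")
  combine <- match.arg(combine)
  if (B < 100L) stop("'B' must be at least 100")
  cp <- to_counting_process(histories)
  point <- rauch_estimate(cp, scheme, t, combine)$point
  rows_by_id <- split(seq_len(nrow(cp)), as.character(cp$id))
  grp_by_id <- vapply(rows_by_id, function(r) cp$group[r[1L]], integer(1))
  ids_I <- names(grp_by_id)[grp_by_id == 1L]
  ids_C <- names(grp_by_id)[grp_by_id == 0L]
  est <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    take <- c(sample(ids_I, length(ids_I), replace = TRUE),
              sample(ids_C, length(ids_C), replace = TRUE))
    picked <- rows_by_id[take]
    bcp <- cp[unlist(picked, use.names = FALSE), , drop = FALSE]
    # resampled subjects must stay distinct even when drawn repeatedly
    bcp$id <- rep(seq_along(picked), lengths(picked))
    est[b] <- tryCatch(rauch_estimate(bcp, scheme, t, combine)$point,
                       error = function(e) NA_real_)
  }
  nfail <- sum(is.na(est))
  if (nfail > 0.2 * B)
    stop(sprintf("bootstrap failed in %d of %d resamples", nfail, B))
  ci <- stats::quantile(est, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  effect_estimate(point, ci[1L], ci[2L], level = 1 - 2 * alpha,
                  method = "Rauch")
}
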