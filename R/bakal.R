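## Bakal weighted Kaplan-Meier approach.
##
## Every subject starts with an individual score of 1 (fully at risk);
## each own event at a pooled event time depletes the score
## multiplicatively by the event-type weight, so a non-fatal event counts
## as a partial event and a fatal event (weight 1) removes the subject.
## Weighted event totals and risk sets are sums of these scores; a
## censored subject's remaining score leaves the sums strictly after its
## censoring time, while its earlier partial events remain counted.
## There is no estimand and hence no effect estimator for this approach:
## only the weighted survival curves and the modified log-rank test are
## provided.

#' Bakal individual scores and weighted risk/event totals
#'
#' Computes, on the pooled (not strata-specific) grid of distinct event
#' times, the weighted event totals `e_k` and weighted numbers at risk
#' `n_k`, pooled and per treatment group.  A subject with no own event at
#' a time keeps its score (its event weight there is zero); all
#' same-time updates are applied simultaneously.
#'
#' @param histories An [event_histories()] object.
#' @param scheme A `"bakal"` [weight_scheme()].
#' @return An object of class `bakal_state`: list with `time` (pooled
#'   event-time grid), `e`, `n` (pooled weighted events and risk sets),
#'   `e_I`, `n_I`, `e_C`, `n_C` (group-specific), `n_subjects`, and
#'   `final_scores` (named per-subject scores at end of observation).
#' @export
bakal_scores <- function(histories, scheme) {
  stopifnot_scheme(scheme, "bakal")
  ids <- unique(histories$id)
  n_sub <- length(ids)
  ev_time <- numeric(0); ev_drop <- numeric(0); ev_group <- integer(0)
  rm_time <- numeric(n_sub); rm_score <- numeric(n_sub)
  sub_group <- integer(n_sub); final <- numeric(n_sub)
  kk <- 0L
  for (rows in split(seq_len(nrow(histories)), factor(histories$id, levels = ids))) {
    kk <- kk + 1L
    st <- histories$status[rows]; tm <- histories$time[rows]
    g <- histories$group[rows[1L]]
    isev <- st != STATUS_CENSORED
    w <- ifelse(st[isev] == STATUS_FATAL, scheme$w_fatal, scheme$w_nonfatal)
    s_path <- cumprod(1 - w)
    s_prev <- c(1, s_path[-length(s_path)])[seq_along(w)]
    ev_time <- c(ev_time, tm[isev])
    ev_drop <- c(ev_drop, s_prev * w)
    ev_group <- c(ev_group, rep(g, sum(isev)))
    sub_group[kk] <- g
    final[kk] <- if (length(s_path)) s_path[length(s_path)] else 1
    rm_time[kk] <- tm[length(rows)]   # end of observation (censor or death)
    rm_score[kk] <- final[kk]
  }
  grid <- sort(unique(ev_time))
  k <- length(grid)
  totals <- function(sel_ev, sel_sub) {
    e <- indexed_sum(ev_drop[sel_ev], match(ev_time[sel_ev], grid), k)
    ct <- c(ev_time[sel_ev], rm_time[sel_sub])
    cv <- c(-ev_drop[sel_ev], -rm_score[sel_sub])
    ord <- order(ct)
    cs <- cumsum(cv[ord])
    cnt <- findInterval(grid, ct[ord], left.open = TRUE)
    n <- sum(sel_sub) + ifelse(cnt == 0L, 0, cs[pmax(cnt, 1L)])
    list(e = e, n = pmax(n, 0))
  }
  pooled <- totals(rep(TRUE, length(ev_time)), rep(TRUE, n_sub))
  gI <- totals(ev_group == 1L, sub_group == 1L)
  gC <- totals(ev_group == 0L, sub_group == 0L)
  structure(list(time = grid, e = pooled$e, n = pooled$n,
                 e_I = gI$e, n_I = gI$n, e_C = gC$e, n_C = gC$n,
                 n_subjects = n_sub,
                 final_scores = stats::setNames(final, ids)),
            class = "bakal_state")
}

#' @export
print.bakal_state <- function(x, ...) {
  cat(sprintf("Bakal state: %d subjects, %d pooled event times, total weighted events %.3f\n",
              x$n_subjects, length(x$time), sum(x$e)))
  invisible(x)
}

#' Weighted Kaplan-Meier survival curves
#'
#' Recursive product-limit curves built from the weighted event totals
#' and risk sets, pooled and per treatment group (group curves use only
#' in-group subjects and weights).  Curves start at 1 and are
#' non-increasing; times where a group has no risk mass contribute a
#' factor of 1.
#'
#' @param state A [bakal_scores()] state.
#' @return A data frame of class `bakal_km` with columns `time`,
#'   `pooled`, `intervention`, `control`.
#' @export
bakal_weighted_km <- function(state) {
  curve <- function(e, n) {
    if (any(e > 1e-12 & n <= 1e-12))
      stop("weighted events at a time with empty weighted risk set")
    frac <- ifelse(n > 1e-12, e / n, 0)
    cumprod(1 - frac)
  }
  structure(
    data.frame(time = state$time,
               pooled = curve(state$e, state$n),
               intervention = curve(state$e_I, state$n_I),
               control = curve(state$e_C, state$n_C)),
    class = c("bakal_km", "data.frame"))
}

#' Modified (weighted) log-rank test
#'
#' One-sided test comparing the weighted survival of the intervention
#' against the control group.  Over the pooled event-time grid the
#' numerator accumulates `e_I - n_I e / n` and the variance the
#' hypergeometric-style terms `n_I n_C (n - e) e / (n^2 (n - 1))`, all
#' computed from the weighted event totals and risk sets; times with
#' pooled weighted risk mass `n <= 1` contribute no variance and are
#' skipped.  With all weights 1 the statistic is the classical log-rank
#' statistic on time-to-first-event data.  It is treated as standard
#' normal under the null of equal weighted survival and rejects in
#' favour of the intervention when `<= -z_(1-alpha)`.
#'
#' @param state A [bakal_scores()] state.
#' @param alpha One-sided significance level (default 0.025).
#' @return A [test_result()].
#' @export
bakal_test <- function(state, alpha = 0.025) {
  use <- state$n > 1
  if (!any(use))
    stop("no pooled event time with weighted risk mass above 1")
  num <- sum((state$e_I - state$n_I * state$e / state$n)[use])
  var <- sum((state$n_I * state$n_C * (state$n - state$e) * state$e /
                (state$n^2 * (state$n - 1)))[use])
  if (var <= 0)
    stop("zero variance in the modified log-rank test")
  test_result(num / sqrt(var), alpha, method = "Bakal")
}
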