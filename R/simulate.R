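## Recurrent-event simulation engine.
##
## A subject's fatal time is drawn by inverting the cumulative hazard at
## an Exp(1) deviate; recurrent non-fatal events are drawn sequentially on
## the calendar (total-time) scale by conditional inversion: given the
## current time s, the next event time t solves
## Lambda(t) = Lambda(s) + Exp(1).  The two processes are independent
## given the treatment group, and death terminates observation.

#' Draw a fatal event time
#'
#' Inverse-transform draw from the distribution with cumulative hazard
#' given by `form`, i.e. survival `exp(-Lambda(t))`.
#'
#' @param form A [hazard_form()] object.
#' @param n Number of draws.
#' @return Numeric vector of event times.
#' @export
draw_fatal_time <- function(form, n = 1L) {
  inv_cum_hazard(form, stats::rexp(n))
}

#' Draw the next recurrent event time on the calendar scale
#'
#' Given the current calendar time `s`, returns `t > s` with conditional
#' survival `exp(-(Lambda(t) - Lambda(s)))`, by inverting the cumulative
#' hazard at `Lambda(s) + Exp(1)`.
#'
#' @param form A [hazard_form()] object.
#' @param s Current calendar time(s), `>= 0`.
#' @return Numeric vector of next event times, elementwise `> s`.
#' @export
draw_next_recurrent_time <- function(form, s) {
  if (any(s < 0)) stop("'s' must be non-negative")
  inv_cum_hazard(form, cum_hazard(form, s) + stats::rexp(length(s)))
}

#' Simulate a two-arm recurrent-event dataset
#'
#' Generates one dataset under a simulation scenario: per subject, a
#' fatal time from the group's fatal hazard and a sequence of non-fatal
#' events from the group's recurrent hazard on the calendar scale,
#' administratively censored at the horizon.  Non-fatal events strictly
#' before `min(fatal time, horizon)` are retained; the fatal event is
#' recorded if it falls within the horizon, otherwise the subject is
#' censored at the horizon.  A per-subject cap bounds the number of
#' recorded events; a capped subject is censored at the horizon.
#'
#' @param spec A [scenario_spec()] (see also [scenario_catalog()]).
#' @return An [event_histories()] object with `2 * spec$n_per_group`
#'   subjects, ids `I1..In` and `C1..Cn`.
#' @examples
#' set.seed(1)
#' h <- simulate_dataset(get_scenario("1a"))
#' table(h$status)
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n_per_group
  horizon <- spec$horizon
  cap <- spec$max_events
  ids <- character(0); times <- numeric(0); statuses <- integer(0)
  groups <- integer(0)
  for (g in c(1L, 0L)) {
    form_M <- if (g == 1L) spec$hazards$I_nonfatal else spec$hazards$C_nonfatal
    form_D <- if (g == 1L) spec$hazards$I_fatal else spec$hazards$C_fatal
    td <- draw_fatal_time(form_D, n)
    for (i in seq_len(n)) {
      end <- min(td[i], horizon)
      ev <- numeric(0)
      s <- 0
      while (length(ev) < cap) {
        s <- draw_next_recurrent_time(form_M, s)
        if (s >= end) break
        ev[length(ev) + 1L] <- s
      }
      capped <- length(ev) >= cap
      if (!capped && td[i] <= horizon) {
        tm <- c(ev, td[i]); st <- c(rep(STATUS_NONFATAL, length(ev)), STATUS_FATAL)
      } else {
        tm <- c(ev, horizon); st <- c(rep(STATUS_NONFATAL, length(ev)), STATUS_CENSORED)
      }
      ids <- c(ids, rep(paste0(if (g == 1L) "I" else "C", i), length(tm)))
      groups <- c(groups, rep(g, length(tm)))
      times <- c(times, tm)
      statuses <- c(statuses, st)
    }
  }
  event_histories(
    data.frame(id = ids, group = groups, time = times, status = statuses),
    horizon = horizon)
}
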