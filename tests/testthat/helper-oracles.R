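# Independent brute-force oracles, written for transparency rather than
# speed; they share no code path with the package implementations.

# stratified Breslow log partial likelihood, evaluated by direct
# enumeration of risk sets
oracle_partial_loglik <- function(beta, cp) {
  ll <- 0
  for (j in unique(cp$stratum)) {
    s <- cp[cp$stratum == j, ]
    for (r in which(s$status > 0)) {
      tt <- s$stop[r]
      atrisk <- s$start < tt & s$stop >= tt
      ll <- ll + beta * s$group[r] - log(sum(exp(beta * s$group[atrisk])))
    }
  }
  ll
}

# two-stage grid search maximizer of the stratified partial likelihood
oracle_grid_beta <- function(cp, cause_code) {
  d <- cp
  d$status <- as.integer(d$status == cause_code)
  coarse <- seq(-5, 5, by = 0.01)
  b0 <- coarse[which.max(vapply(coarse, oracle_partial_loglik, 0, cp = d))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  fine[which.max(vapply(fine, oracle_partial_loglik, 0, cp = d))]
}

# classical stratified all-cause log-rank statistic on a counting-process
# table, by direct enumeration
oracle_stratified_logrank <- function(cp) {
  num <- 0; var <- 0
  for (j in unique(cp$stratum)) {
    d <- cp[cp$stratum == j, ]
    for (tt in sort(unique(d$stop[d$status > 0]))) {
      atrisk <- d$start < tt & d$stop >= tt
      y <- sum(atrisk); yi <- sum(atrisk & d$group == 1)
      dn <- sum(d$stop == tt & d$status > 0)
      dni <- sum(d$stop == tt & d$status > 0 & d$group == 1)
      if (y <= 1) next
      num <- num + dni - yi / y * dn
      var <- var + yi * (y - yi) / y^2 * (y - dn) / (y - 1) * dn
    }
  }
  num / sqrt(var)
}

# all-cause Nelson-Aalen cumulative hazard at time t for one group, risk
# set = subjects under observation, every event counted
oracle_pooled_cumhaz <- function(histories, group, t) {
  h <- histories[histories$group == group, , drop = FALSE]
  ends <- tapply(h$time, h$id, max)
  total <- 0
  for (tt in sort(unique(h$time[h$status > 0 & h$time <= t]))) {
    d <- sum(h$time == tt & h$status > 0)
    y <- sum(ends >= tt)
    total <- total + d / y
  }
  total
}

# time-to-first-event view: one row per subject with any-event indicator
first_event_table <- function(histories) {
  do.call(rbind, lapply(split(as.data.frame(histories), histories$id),
    function(d) {
      ev <- d$status > 0
      data.frame(group = d$group[1],
                 time = if (any(ev)) d$time[ev][1] else max(d$time),
                 status = as.integer(any(ev)))
    }))
}

# signed classical log-rank on first-event data via survival::survdiff
oracle_first_event_logrank <- function(histories) {
  one <- first_event_table(histories)
  sd1 <- survival::survdiff(survival::Surv(time, status) ~ group, data = one)
  (sd1$obs[2] - sd1$exp[2]) / sqrt(sd1$var[2, 2])
}

# small random recurrent-event dataset for property-style tests
random_histories <- function(n_per_group = 30, scenario = "1a") {
  simulate_dataset(get_scenario(scenario, n_per_group = n_per_group))
}

null_scenario <- function(n_per_group = 100) {
  c25 <- hazard_form("constant", 0.25)
  scenario_spec("null",
                list(I_nonfatal = c25, I_fatal = c25,
                     C_nonfatal = c25, C_fatal = c25),
                list(weilachin = weight_scheme("weilachin", 0.5263, 0.4737),
                     rauch = weight_scheme("rauch", 1, 0.9),
                     bakal = weight_scheme("bakal", 1, 0.9)),
                hr_nonfatal = 1, hr_fatal = 1, n_per_group = n_per_group)
}
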