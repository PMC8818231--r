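# hand-constructed fits for closed-form checks of the combined test:
# only the fields used by wl_test / wl_estimate_ci are populated
fake_fit <- function(beta, var) {
  structure(list(beta = beta, var_model = var, var_robust = var,
                 score_resid = NULL, converged = TRUE),
            class = "strat_cox_fit")
}

toy_cp <- function() {
  cp <- data.frame(id = 1:6, group = c(1, 1, 1, 0, 0, 0), stratum = 1L,
                   start = 0, stop = c(1, 2.5, 3, 0.7, 1.8, 2.2),
                   status = c(1L, 0L, 1L, 1L, 1L, 0L))
  structure(cp, class = c("counting_process", "data.frame"), horizon = 3)
}

test_that("stratified Cox fit matches the grid-search partial-likelihood oracle", {
  cp <- toy_cp()
  f <- fit_stratified_cox(cp, "nonfatal")
  expect_true(f$converged)
  expect_equal(f$beta, oracle_grid_beta(cp, 1L), tolerance = 1e-4)
  # multi-stratum simulated table
  set.seed(21)
  cp2 <- to_counting_process(random_histories(15))
  f2 <- fit_stratified_cox(cp2, "nonfatal")
  expect_equal(f2$beta, oracle_grid_beta(cp2, 1L), tolerance = 1e-4)
  f3 <- fit_stratified_cox(cp2, "fatal")
  expect_equal(f3$beta, oracle_grid_beta(cp2, 2L), tolerance = 1e-4)
  # score residuals sum to zero at the maximum
  expect_lt(abs(sum(f2$score_resid)), 1e-6)
})

test_that("Cox fit symmetries: label swap and subject duplication", {
  cp <- toy_cp()
  f <- fit_stratified_cox(cp, "nonfatal")
  swapped <- cp
  swapped$group <- 1L - swapped$group
  fs <- fit_stratified_cox(swapped, "nonfatal")
  expect_equal(fs$beta, -f$beta, tolerance = 1e-8)
  dup <- rbind(cp, transform(cp, id = id + 100L))
  attr(dup, "horizon") <- 3
  fd <- fit_stratified_cox(dup, "nonfatal")
  expect_equal(fd$beta, f$beta, tolerance = 1e-8)
  expect_equal(fd$var_model, f$var_model / 2, tolerance = 1e-8)
})

test_that("degenerate fits are flagged for exclusion", {
  cp <- toy_cp()
  cp$status[cp$status == 1L & cp$group == 0L] <- 0L  # events only in group 1
  f <- fit_stratified_cox(cp, "nonfatal")
  expect_false(f$converged)
  expect_false(fit_stratified_cox(toy_cp(), "fatal")$converged)  # no deaths
})

test_that("cross-cause covariance: identity case and hand-sized data", {
  set.seed(22)
  cp <- to_counting_process(random_histories(25))
  fM <- fit_stratified_cox(cp, "nonfatal")
  # same cause twice: covariance equals the robust variance
  expect_equal(wl_covariance(fM, fM), fM$var_robust, tolerance = 1e-12)
  # hand evaluation from the residuals and informations
  fD <- fit_stratified_cox(cp, "fatal")
  expect_equal(wl_covariance(fD, fM),
               sum(fD$score_resid * fM$score_resid) /
                 (fD$information * fM$information), tolerance = 1e-12)
})

test_that("stacked covariance tracks the empirical covariance of the estimators", {
  set.seed(23)
  spec <- get_scenario("1a", n_per_group = 50)
  R <- 250
  bD <- bM <- sDM <- rep(NA_real_, R)
  for (r in seq_len(R)) {
    cp <- to_counting_process(simulate_dataset(spec))
    fD <- fit_stratified_cox(cp, "fatal")
    fM <- fit_stratified_cox(cp, "nonfatal")
    if (!fD$converged || !fM$converged) next
    bD[r] <- fD$beta; bM[r] <- fM$beta
    sDM[r] <- wl_covariance(fD, fM)
  }
  ok <- !is.na(bD)
  emp <- stats::cov(bD[ok], bM[ok])
  prods <- (bD[ok] - mean(bD[ok])) * (bM[ok] - mean(bM[ok]))
  se_emp <- stats::sd(prods) / sqrt(sum(ok))
  expect_lt(abs(mean(sDM[ok]) - emp), 3 * se_emp)
})

test_that("the weighted statistic, estimate and interval follow the closed forms", {
  fD <- fake_fit(-0.5, 0.04)
  fM <- fake_fit(-0.3, 0.09)
  w <- weight_scheme("weilachin", 0.5, 0.5)
  t <- wl_test(fD, fM, sigma_DM = 0.01, scheme = w)
  expect_equal(t$statistic, -0.4 / sqrt(0.0375), tolerance = 1e-10)
  expect_equal(t$statistic, -2.0656, tolerance = 1e-4)
  expect_true(t$reject)
  expect_equal(t$p_one_sided, stats::pnorm(t$statistic))
  est <- wl_estimate_ci(fD, fM, sigma_DM = 0.01, scheme = w)
  expect_equal(est$point, 0.6703, tolerance = 1e-4)
  expect_equal(est$ci_lower, 0.4586, tolerance = 1e-4)
  expect_equal(est$ci_upper, 0.9798, tolerance = 1e-4)
  # vanishing variance collapses the interval onto the point
  est0 <- wl_estimate_ci(fake_fit(-0.5, 1e-18), fake_fit(-0.3, 1e-18),
                         sigma_DM = 0, scheme = w)
  expect_equal(est0$ci_lower, est0$point, tolerance = 1e-6)
  # single-cause limit (validation relaxed on purpose)
  w10 <- structure(list(method = "weilachin", w_fatal = 1, w_nonfatal = 0),
                   class = "weight_scheme")
  expect_equal(wl_test(fD, fM, sigma_DM = 0.01, scheme = w10)$statistic,
               -0.5 / 0.2, tolerance = 1e-10)
  expect_error(wl_test(fD, fM, 0.01, weight_scheme("rauch", 1, 1)), "weilachin")
})

test_that("the true weighted hazard ratio reproduces tabulated estimands", {
  w <- weight_scheme("weilachin", 0.5263, 0.4737)
  expect_equal(round(wl_true_theta(0.7, 0.5, w), 2), 0.60)
  expect_equal(round(wl_true_theta(0.7, 1.5, w), 2), 1.00)
  expect_equal(wl_true_theta(0.8, 0.8, w), 0.8, tolerance = 1e-12)
  expect_error(wl_true_theta(-1, 0.5, w), "positive")
})

test_that("with one event type the analysis reduces to that cause's Cox model", {
  set.seed(24)
  h <- random_histories(40)
  h$status[h$status == 2L] <- 0L  # drop the fatal events
  # drop rows that became duplicate terminal rows
  keep <- !duplicated(paste(h$id, h$status == 0L)) | h$status != 0L
  h <- event_histories(h[keep, ], horizon = 3)
  cp <- to_counting_process(h)
  fM <- fit_stratified_cox(cp, "nonfatal")
  w <- structure(list(method = "weilachin", w_fatal = 0, w_nonfatal = 1),
                 class = "weight_scheme")
  est <- wl_estimate_ci(fake_fit(0, 0), fM, sigma_DM = 0, scheme = w)
  expect_equal(est$point, exp(fM$beta), tolerance = 1e-12)
})

test_that("the weighted statistic is invariant to rescaling time", {
  set.seed(25)
  h <- random_histories(30)
  w <- weight_scheme("weilachin", 0.6667, 0.3333)
  run <- function(hh) {
    cp <- to_counting_process(hh)
    a <- weilachin_analysis(cp, w)
    a$test$statistic
  }
  h_days <- h
  h_days$time <- h$time * 365.25
  attr(h_days, "horizon") <- 3 * 365.25
  expect_equal(run(h), run(h_days), tolerance = 1e-8)
})
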