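test_that("cumulative hazards invert in closed form", {
  expect_equal(inv_cum_hazard(hazard_form("constant", 0.25), 0.75), 3)
  expect_equal(inv_cum_hazard(hazard_form("linear", 0.1), 0.2), 2)
  expect_equal(inv_cum_hazard(hazard_form("power", 0.192, -0.2), 0.24), 1)
  expect_error(inv_cum_hazard(hazard_form("constant", 0.25), -1), "non-negative")
  # round trip at random arguments, all shapes
  set.seed(3)
  for (f in list(hazard_form("constant", 0.4), hazard_form("linear", 0.07),
                 hazard_form("power", 0.3, -0.4), hazard_form("power", 2, 1.5))) {
    y <- stats::runif(50, 0, 5)
    expect_equal(cum_hazard(f, inv_cum_hazard(f, y)), y, tolerance = 1e-10)
  }
})

test_that("fatal draws follow the survival function exp(-Lambda)", {
  set.seed(11)
  n <- 1e4
  # exponential case: KS against the closed-form cdf and the mean 1/a
  x <- draw_fatal_time(hazard_form("constant", 0.25), n)
  expect_gt(stats::ks.test(x, stats::pexp, rate = 0.25)$p.value, 0.01)
  expect_lt(abs(mean(x) - 4), 3 * stats::sd(x) / sqrt(n))
  # Weibull-type power hazard
  f <- hazard_form("power", 0.192, -0.2)
  y <- draw_fatal_time(f, n)
  expect_gt(stats::ks.test(y, function(q) 1 - exp(-cum_hazard(f, q)))$p.value,
            0.01)
})

test_that("recurrent draws have the right conditional law on the calendar scale", {
  set.seed(12)
  n <- 1e4
  # memorylessness for the constant hazard: t - s ~ Exp(a), any s
  g <- draw_next_recurrent_time(hazard_form("constant", 0.2), rep(5, n)) - 5
  expect_gt(stats::ks.test(g, stats::pexp, rate = 0.2)$p.value, 0.01)
  # general shape: Lambda(t) - Lambda(s) ~ Exp(1)
  f <- hazard_form("linear", 0.1)
  s <- 2
  t2 <- draw_next_recurrent_time(f, rep(s, n))
  expect_true(all(t2 > s))
  expect_gt(stats::ks.test(cum_hazard(f, t2) - cum_hazard(f, s),
                           stats::pexp, rate = 1)$p.value, 0.01)
})

test_that("simulated cohorts match closed-form event moments", {
  set.seed(13)
  spec <- get_scenario("1a", n_per_group = 4000)
  h <- simulate_dataset(spec)
  # fatal-event frequency per arm: 1 - exp(-Lambda_D(3))
  for (g in 0:1) {
    rate <- if (g == 1) 0.125 else 0.25
    p <- 1 - exp(-3 * rate)
    ids_g <- unique(h$id[h$group == g])
    dead <- ids_g %in% h$id[h$status == 2]
    expect_lt(abs(mean(dead) - p), 3 * sqrt(p * (1 - p) / 4000))
  }
  # among subjects censored at the horizon, the non-fatal count is
  # Poisson(Lambda_M(3)): check mean and index of dispersion
  ids_cens <- unique(h$id[h$status == 0 & h$time == 3 & h$group == 0])
  k <- tabulate(factor(h$id[h$status == 1], levels = ids_cens))
  lam <- 0.25 * 3
  expect_lt(abs(mean(k) - lam), 3 * sqrt(lam / length(ids_cens)))
  disp <- stats::var(k) / mean(k)
  expect_lt(abs(disp - 1), 3 * sqrt(2 / length(ids_cens)))
})

test_that("simulation is bit-reproducible under a fixed seed", {
  set.seed(99); h1 <- simulate_dataset(get_scenario("3b", n_per_group = 20))
  set.seed(99); h2 <- simulate_dataset(get_scenario("3b", n_per_group = 20))
  expect_identical(h1, h2)
})

test_that("the scenario catalog transcribes the study grid", {
  cat55 <- scenario_catalog()
  expect_length(cat55, 55L)
  s1a <- cat55[["1a"]]
  expect_equal(s1a$hazards$C_nonfatal$a, 0.25)
  expect_equal(s1a$hazards$I_fatal$a, 0.125)   # 0.25 * 0.5
  expect_equal(s1a$weights$weilachin$w_fatal, 0.5263)
  expect_equal(s1a$weights$weilachin$w_nonfatal, 0.4737)
  expect_equal(s1a$weights$rauch$w_nonfatal, 0.9)
  expect_equal(s1a$n_per_group, 100L)
  expect_equal(s1a$horizon, 3)
  s6c <- get_scenario("6c")
  expect_equal(s6c$hazards$I_fatal$shape, "linear")
  expect_equal(s6c$hazards$I_fatal$a, 0.1 * 0.7)
  expect_equal(s6c$hazards$I_nonfatal$a, 0.25 * 0.5)
  expect_equal(s6c$weights$rauch$w_nonfatal, 0.5)
  s10a <- get_scenario("10a")
  expect_equal(s10a$hazards$I_nonfatal[c("a", "b")], list(a = 0.192, b = -0.2))
  expect_equal(s10a$hazards$I_fatal[c("a", "b")], list(a = 0.084, b = -0.3))
  expect_equal(s10a$hazards$C_nonfatal[c("a", "b")], list(a = 0.28, b = -0.3))
  expect_equal(s10a$hazards$C_fatal[c("a", "b")], list(a = 0.32, b = -0.2))
  expect_error(get_scenario("12a"), "unknown scenario")
  expect_error(get_scenario("1f"), "unknown scenario")
})
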