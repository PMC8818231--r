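test_that("weight schemes enforce the method-specific constraints", {
  expect_s3_class(weight_scheme("weilachin", 0.5263, 0.4737), "weight_scheme")
  expect_s3_class(weight_scheme("rauch", 1, 0.5), "weight_scheme")
  expect_s3_class(weight_scheme("bakal", 1, 0.1), "weight_scheme")
  expect_error(weight_scheme("weilachin", 0.6, 0.6), "sum to 1")
  expect_error(weight_scheme("weilachin", 1, 0), "strictly positive")
  expect_error(weight_scheme("rauch", -0.1, 0.5), "non-negative")
  expect_error(weight_scheme("rauch", 0, 0), "both be zero")
  expect_error(weight_scheme("bakal", 1, 1.2), "\\[0, 1\\]")
})

test_that("event histories validate subject-level invariants", {
  h <- event_histories(data.frame(
    id = c("a", "a", "b"), group = c(1, 1, 0),
    time = c(1, 2.5, 3), status = c(1, 2, 0)), horizon = 3)
  expect_s3_class(h, "event_histories")
  # non-fatal row may not be terminal
  expect_error(event_histories(data.frame(
    id = "a", group = 1, time = 1, status = 1)), "terminal")
  # at most one terminal row
  expect_error(event_histories(data.frame(
    id = c("a", "a"), group = 1, time = c(2, 3), status = c(0, 0))),
    "duplicate terminal")
  # fatal event must be last
  expect_error(event_histories(data.frame(
    id = c("a", "a"), group = 1, time = c(1, 2), status = c(2, 1))),
    "terminal")
  # strictly increasing event times
  expect_error(event_histories(data.frame(
    id = c("a", "a", "a"), group = 1, time = c(1, 1, 3),
    status = c(1, 1, 0))), "strictly increasing")
  # horizon bound
  expect_error(event_histories(data.frame(
    id = "a", group = 1, time = 4, status = 0), horizon = 3), "horizon")
  expect_error(event_histories(data.frame(
    id = "a", group = 1, time = 2, status = 7)), "status")
})

test_that("counting-process conversion follows the stratification rule", {
  # death as second event lands in the second stratum
  h <- event_histories(data.frame(
    id = c("a", "a"), group = 1, time = c(1, 2.5), status = c(1, 2)),
    horizon = 3)
  cp <- to_counting_process(h)
  expect_equal(cp$stratum, c(1L, 2L))
  expect_equal(cp$start, c(0, 1))
  expect_equal(cp$stop, c(1, 2.5))
  expect_equal(cp$status, c(1L, 2L))

  # no events: single censored row in stratum 1
  h0 <- event_histories(data.frame(id = "a", group = 0, time = 3, status = 0))
  cp0 <- to_counting_process(h0)
  expect_equal(nrow(cp0), 1L)
  expect_equal(cp0$stratum, 1L)
  expect_equal(cp0$stop, 3)
  expect_equal(cp0$status, 0L)

  # non-fatal event then censoring: trailing censored row in stratum 2
  h1 <- event_histories(data.frame(
    id = c("c", "c"), group = 0, time = c(1, 3), status = c(1, 0)))
  cp1 <- to_counting_process(h1)
  expect_equal(cp1$stratum, c(1L, 2L))
  expect_equal(cp1$start, c(0, 1))
  expect_equal(cp1$stop, c(1, 3))
  expect_equal(cp1$status, c(1L, 0L))

  # censoring exactly at the last event adds no trailing row
  h2 <- event_histories(data.frame(
    id = c("d", "d"), group = 0, time = c(2, 2), status = c(1, 0)))
  expect_equal(nrow(to_counting_process(h2)), 1L)
})

test_that("counting-process invariants hold on simulated data", {
  set.seed(41)
  for (rep in 1:10) {
    h <- random_histories(25)
    cp <- to_counting_process(h)
    for (id in unique(h$id)) {
      hr <- h[h$id == id, ]
      cr <- cp[cp$id == id, ]
      # strata consecutive from 1, total-time scale
      expect_equal(cr$stratum, seq_len(nrow(cr)))
      expect_equal(cr$start, c(0, cr$stop[-nrow(cr)]))
      # time on study sums to min(censor, fatal)
      expect_equal(sum(cr$stop - cr$start), max(hr$time))
      # regrouping event rows reconstructs the history
      expect_equal(cr$stop[cr$status > 0], hr$time[hr$status > 0])
      expect_equal(cr$status[cr$status > 0], hr$status[hr$status > 0])
      # stratum count = events (+1 for a trailing censored row)
      n_ev <- sum(hr$status > 0)
      expect_true(nrow(cr) %in% c(n_ev, n_ev + 1L))
      expect_equal(any(cr$status == 0), nrow(cr) == n_ev + 1L)
    }
  }
})

test_that("first-event reduction keeps the earliest event only", {
  h <- event_histories(data.frame(
    id = c("a", "a", "b", "c"), group = c(1, 1, 0, 0),
    time = c(1, 2.5, 2, 3), status = c(1, 2, 2, 0)), horizon = 3)
  r <- first_event_reduction(h)
  a <- r[r$id == "a", ]
  expect_equal(a$time, c(1, 1))          # censored at the first event
  expect_equal(a$status, c(1L, 0L))
  expect_equal(r[r$id == "b", ]$status, 2L)  # fatal first event unchanged
  expect_equal(r[r$id == "c", ]$status, 0L)  # event-free unchanged
  expect_identical(first_event_reduction(r), r)  # idempotent
})

test_that("event CSV write/read round trip is the identity", {
  set.seed(7)
  h <- random_histories(10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(h, path)
  h2 <- read_events_csv(path, horizon = attr(h, "horizon"))
  expect_equal(as.data.frame(h2), as.data.frame(h))
  # unknown status code rejected
  bad <- utils::read.csv(path)
  bad$status[1] <- 7L
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_events_csv(path), "status")
  # header-only file yields an empty collection
  writeLines("id,group,time,status", path)
  expect_equal(nrow(read_events_csv(path)), 0L)
})
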