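## Event-history container.
##
## A collection of subject histories is stored in long format, one row per
## observed event plus one terminal row per subject:
##   id     subject label
##   group  1 = intervention, 0 = control
##   time   years since randomization, > 0
##   status 0 = censored, 1 = non-fatal event, 2 = fatal event
## The terminal row of a subject is either its (single, last) fatal event
## or a status-0 censoring row; a censoring row may share the time of the
## last non-fatal event, all other times are strictly increasing.

STATUS_CENSORED <- 0L
STATUS_NONFATAL <- 1L
STATUS_FATAL    <- 2L

#' Event-history collection
#'
#' Builds a validated collection of subject event histories from a long
#' data frame with columns `id`, `group`, `time`, `status`
#' (0 = censored, 1 = non-fatal, 2 = fatal).  Each subject must end in a
#' terminal row: a fatal event or a censoring row; censoring may coincide
#' with the last non-fatal event, event times are strictly increasing and
#' positive.
#'
#' @param data Data frame with columns `id`, `group`, `time`, `status`.
#' @param horizon Optional administrative censoring horizon in years; when
#'   given, all times must be `<= horizon` and the value is carried as an
#'   attribute so downstream analyses "at the end of study" are
#'   reproducible.
#' @return A data frame of class `event_histories`, rows ordered by
#'   subject and time, with attribute `horizon`.
#' @seealso [to_counting_process()], [read_events_csv()]
#' @export
event_histories <- function(data, horizon = NULL) {
  req <- c("id", "group", "time", "status")
  if (!all(req %in% names(data)))
    stop("'data' must have columns ", paste(req, collapse = ", "))
  data <- as.data.frame(data)[req]
  data$status <- as.integer(data$status)
  data$group <- as.integer(data$group)
  if (nrow(data)) {
    data <- data[order(data$id, data$time, data$status == STATUS_CENSORED), ,
                 drop = FALSE]
    rownames(data) <- NULL
  }
  x <- structure(data, class = c("event_histories", "data.frame"),
                 horizon = if (is.null(horizon)) NA_real_ else as.numeric(horizon))
  validate_histories(x)
}

#' @rdname event_histories
#' @param x An `event_histories` object.
#' @export
validate_histories <- function(x) {
  if (nrow(x) == 0L) return(x)
  if (anyNA(x$time) || anyNA(x$status) || anyNA(x$group) || anyNA(x$id))
    stop("missing values in event histories")
  if (!all(x$status %in% c(STATUS_CENSORED, STATUS_NONFATAL, STATUS_FATAL)))
    stop("unknown status code; expected 0 (censored), 1 (non-fatal), 2 (fatal)")
  if (any(x$time <= 0))
    stop("event and censoring times must be strictly positive")
  if (!all(x$group %in% 0:1))
    stop("group must be 0 (control) or 1 (intervention)")
  horizon <- attr(x, "horizon")
  if (!is.na(horizon) && any(x$time > horizon + 1e-12))
    stop("times exceed the administrative horizon of ", horizon)
  for (rows in split(seq_len(nrow(x)), x$id)) {
    st <- x$status[rows]; tm <- x$time[rows]
    if (length(unique(x$group[rows])) != 1L)
      stop("group label changes within subject ", x$id[rows[1L]])
    n <- length(rows)
    if (st[n] == STATUS_NONFATAL)
      stop("subject ", x$id[rows[1L]],
           " lacks a terminal row (fatal event or censoring)")
    if (sum(st == STATUS_FATAL) > 1L || sum(st == STATUS_CENSORED) > 1L)
      stop("subject ", x$id[rows[1L]], " has duplicate terminal rows")
    if (any(st[-n] != STATUS_NONFATAL))
      stop("subject ", x$id[rows[1L]],
           " has a terminal row before its last observation")
    ev <- tm[st != STATUS_CENSORED]
    if (length(ev) > 1L && any(diff(ev) <= 0))
      stop("event times not strictly increasing for subject ", x$id[rows[1L]])
    if (st[n] == STATUS_CENSORED && n > 1L && tm[n] < tm[n - 1L])
      stop("censoring before last event for subject ", x$id[rows[1L]])
  }
  x
}

#' @export
print.event_histories <- function(x, ...) {
  h <- attr(x, "horizon")
  cat(sprintf("Event histories: %d subjects, %d non-fatal and %d fatal events%s\n",
              length(unique(x$id)), sum(x$status == STATUS_NONFATAL),
              sum(x$status == STATUS_FATAL),
              if (is.na(h)) "" else sprintf(", horizon %g years", h)))
  NextMethod()
}

#' Reduce histories to the time of the first event
#'
#' Keeps, for every subject, only the earliest event of any type (or the
#' censoring when no event occurred); a subject with a first non-fatal
#' event is censored at that event time.  This is the classical
#' time-to-first-event view of the composite endpoint and the reference
#' point for the unit-weight reductions of the Bakal approach.
#'
#' @param histories An [event_histories()] object.
#' @return An `event_histories` object with at most one event per subject.
#' @export
first_event_reduction <- function(histories) {
  out <- vector("list", length(unique(histories$id)))
  k <- 0L
  for (rows in split(seq_len(nrow(histories)), histories$id)) {
    st <- histories$status[rows]
    first <- which(st != STATUS_CENSORED)[1L]
    keep <- if (is.na(first)) rows else rows[seq_len(first)]
    sub <- histories[keep, , drop = FALSE]
    n <- nrow(sub)
    if (sub$status[n] == STATUS_NONFATAL) {
      sub <- rbind(sub, sub[n, , drop = FALSE])
      sub$status[n + 1L] <- STATUS_CENSORED
    }
    k <- k + 1L
    out[[k]] <- sub
  }
  event_histories(do.call(rbind, out), horizon = attr(histories, "horizon"))
}

#' Read or write event histories as CSV
#'
#' The CSV layout is the long format documented in [event_histories()]:
#' columns `id`, `group`, `time`, `status` with status codes 0 (censored),
#' 1 (non-fatal), 2 (fatal), one row per event plus one terminal row per
#' subject.  Times are written with full precision so that a write/read
#' round trip is the identity.
#'
#' @param path File path.
#' @param histories An [event_histories()] object.
#' @param horizon Optional horizon passed to [event_histories()] on read.
#' @return `read_events_csv()` returns an `event_histories` object;
#'   `write_events_csv()` returns `path` invisibly.
#' @export
read_events_csv <- function(path, horizon = NULL) {
  data <- utils::read.csv(path, colClasses = c(
    id = "character", group = "integer", time = "numeric", status = "integer"))
  event_histories(data, horizon = horizon)
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(histories, path) {
  df <- as.data.frame(histories)
  df$time <- format(df$time, digits = 15, scientific = FALSE, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
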