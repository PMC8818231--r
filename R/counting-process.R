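#' Stratified counting-process representation
#'
#' Converts event histories to the stratified (start, stop] counting
#' process used by all stratified analyses: stratum j collects every
#' subject's j-th composite event, so all first events fall in stratum 1,
#' all second events in stratum 2, and so on (a death occurring as the
#' second event belongs to the second stratum).  Intervals are on the
#' total-time (calendar) scale: the j-th interval starts at the time of
#' the (j-1)-th event, so a subject re-enters the risk set of the next
#' stratum immediately after a non-fatal event.
#'
#' Each subject contributes one row per experienced event plus, unless the
#' last observation is a fatal event or an event exactly at the censoring
#' time, a trailing censored row from the last event to the censoring
#' time.
#'
#' @param histories An [event_histories()] object.
#' @param horizon Administrative horizon in years carried as metadata;
#'   defaults to the horizon of `histories`.
#' @return A data frame of class `counting_process` with columns `id`,
#'   `group`, `stratum`, `start`, `stop`, `status` (0 = censored within
#'   the stratum, 1 = non-fatal, 2 = fatal) and attribute `horizon`.
#' @examples
#' h <- event_histories(data.frame(
#'   id = c(1, 1, 2), group = c(1, 1, 0), time = c(1, 2.5, 3),
#'   status = c(1, 2, 0)), horizon = 3)
#' to_counting_process(h)
#' @export
to_counting_process <- function(histories, horizon = attr(histories, "horizon")) {
  validate_histories(histories)
  id <- histories$id; time <- histories$time; status <- histories$status
  n <- nrow(histories)
  if (n == 0L)
    return(empty_counting_process(horizon))
  ## order is by subject then time (constructor invariant); a trailing
  ## censored row whose time equals the last event is a zero-length
  ## interval and is dropped.
  first <- !duplicated(id)
  start <- c(0, time[-n])
  start[first] <- 0
  stratum <- sequence(tabulate(factor(id, levels = unique(id))))
  keep <- time > start | status != STATUS_CENSORED
  if (any(time[keep] <= start[keep]))
    stop("zero-length at-risk interval for an event row")
  cp <- data.frame(id = id[keep], group = histories$group[keep],
                   stratum = stratum[keep], start = start[keep],
                   stop = time[keep], status = status[keep])
  structure(cp, class = c("counting_process", "data.frame"),
            horizon = if (is.null(horizon)) NA_real_ else as.numeric(horizon))
}

empty_counting_process <- function(horizon = NA_real_) {
  structure(
    data.frame(id = character(0), group = integer(0), stratum = integer(0),
               start = numeric(0), stop = numeric(0), status = integer(0)),
    class = c("counting_process", "data.frame"),
    horizon = as.numeric(horizon))
}

#' @export
print.counting_process <- function(x, ...) {
  cat(sprintf("Counting process: %d rows, %d subjects, %d strata\n",
              nrow(x), length(unique(x$id)), max(c(0L, x$stratum))))
  NextMethod()
}

#' Write a counting-process table as CSV
#'
#' Writes the stratified (start, stop] table in a layout directly usable
#' by standard survival software: columns `id`, `group`, `stratum`,
#' `start`, `stop`, `status`.
#'
#' @param cp A [to_counting_process()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_counting_process_csv <- function(cp, path) {
  df <- as.data.frame(cp)
  df$start <- format(df$start, digits = 15, scientific = FALSE, trim = TRUE)
  df$stop <- format(df$stop, digits = 15, scientific = FALSE, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
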