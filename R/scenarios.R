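## Simulation scenario catalog.
##
## Eleven hazard configurations crossed with five weight settings (a-e)
## give 55 scenarios.  The four hazards (cause x group) share their shape
## across strata: the risk of a subsequent event does not change after an
## event, and treatment effects are common to all strata.  In the
## proportional-hazards configurations 1-9 the intervention hazards are
## the control hazards scaled by constant cause-specific hazard ratios;
## configurations 10-11 use Weibull hazards with non-proportional
## cause-specific effects.

# control baselines and cause-specific hazard ratios per configuration;
# NULL hr marks the non-proportional Weibull configurations
scenario_base <- function(num) {
  const25 <- hazard_form("constant", 0.25)
  lin01 <- hazard_form("linear", 0.1)
  prop <- function(base_M, base_D, hr_M, hr_D) {
    list(hazards = list(I_nonfatal = scale_hazard(base_M, hr_M),
                        I_fatal = scale_hazard(base_D, hr_D),
                        C_nonfatal = base_M, C_fatal = base_D),
         hr_nonfatal = hr_M, hr_fatal = hr_D)
  }
  switch(as.character(num),
    "1" = prop(const25, const25, 0.5, 0.5),
    "2" = prop(const25, const25, 0.5, 0.7),
    "3" = prop(const25, const25, 0.7, 0.5),
    "4" = prop(const25, const25, 1.5, 0.7),
    "5" = prop(const25, const25, 0.7, 1.5),
    "6" = prop(const25, lin01, 0.5, 0.7),
    "7" = prop(const25, lin01, 0.7, 0.5),
    "8" = prop(lin01, const25, 0.5, 0.7),
    "9" = prop(lin01, const25, 0.7, 0.5),
    "10" = list(hazards = list(I_nonfatal = hazard_form("power", 0.192, -0.2),
                               I_fatal = hazard_form("power", 0.084, -0.3),
                               C_nonfatal = hazard_form("power", 0.28, -0.3),
                               C_fatal = hazard_form("power", 0.32, -0.2)),
                hr_nonfatal = NA_real_, hr_fatal = NA_real_),
    "11" = list(hazards = list(I_nonfatal = hazard_form("power", 0.084, -0.3),
                               I_fatal = hazard_form("power", 0.192, -0.2),
                               C_nonfatal = hazard_form("power", 0.32, -0.2),
                               C_fatal = hazard_form("power", 0.28, -0.3)),
                hr_nonfatal = NA_real_, hr_fatal = NA_real_),
    stop("unknown scenario number: ", num))
}

# weight settings a-e: Wei-Lachin pairs sum to 1 with the same
# fatal/non-fatal ratio as the Rauch/Bakal pairs (1, w_nonfatal)
weight_setting <- function(letter) {
  wl <- switch(letter,
    a = c(0.5263, 0.4737), b = c(0.5882, 0.4118), c = c(0.6667, 0.3333),
    d = c(0.7692, 0.2308), e = c(0.9091, 0.0909),
    stop("unknown weight setting: ", letter))
  rb <- switch(letter, a = 0.9, b = 0.7, c = 0.5, d = 0.3, e = 0.1)
  list(weilachin = weight_scheme("weilachin", wl[1L], wl[2L]),
       rauch = weight_scheme("rauch", 1, rb),
       bakal = weight_scheme("bakal", 1, rb))
}

#' Simulation scenario specification
#'
#' A scenario bundles the four cause- and group-specific hazards, the
#' weight schemes for the three analysis approaches, and the trial
#' layout (subjects per arm, follow-up horizon, per-subject event cap).
#'
#' @param id Scenario label, e.g. `"2a"`.
#' @param hazards Named list of four [hazard_form()] objects:
#'   `I_nonfatal`, `I_fatal`, `C_nonfatal`, `C_fatal`.
#' @param weights Named list of three [weight_scheme()] objects:
#'   `weilachin`, `rauch`, `bakal`.
#' @param hr_nonfatal,hr_fatal Constant cause-specific hazard ratios when
#'   the effects are proportional, `NA` otherwise.
#' @param n_per_group Subjects per arm (default 100).
#' @param horizon Administrative censoring horizon in years (default 3).
#' @param max_events Per-subject event cap (default 100).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(id, hazards, weights, hr_nonfatal = NA_real_,
                          hr_fatal = NA_real_, n_per_group = 100L,
                          horizon = 3, max_events = 100L) {
  stopifnot(n_per_group >= 1L, horizon > 0, max_events >= 1L)
  stopifnot(setequal(names(hazards),
                     c("I_nonfatal", "I_fatal", "C_nonfatal", "C_fatal")))
  for (f in hazards) stopifnot(inherits(f, "hazard_form"))
  structure(list(id = id, hazards = hazards, weights = weights,
                 hr_nonfatal = hr_nonfatal, hr_fatal = hr_fatal,
                 n_per_group = as.integer(n_per_group), horizon = horizon,
                 max_events = as.integer(max_events)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario %s> n/arm = %d, horizon = %g y\n",
              x$id, x$n_per_group, x$horizon))
  invisible(x)
}

#' Scenario catalog
#'
#' `scenario_catalog()` returns all 55 study scenarios (hazard
#' configurations 1-11 crossed with weight settings a-e);
#' `get_scenario()` retrieves a single one by id.
#'
#' @param id Scenario id such as `"1a"` or `"10e"`.
#' @param n_per_group,horizon,max_events Trial layout, passed to
#'   [scenario_spec()].
#' @return A named list of [scenario_spec()] objects, or a single spec.
#' @examples
#' get_scenario("6c")$hazards$I_fatal
#' @export
scenario_catalog <- function(n_per_group = 100L, horizon = 3,
                             max_events = 100L) {
  out <- list()
  for (num in 1:11) {
    base <- scenario_base(num)
    for (letter in c("a", "b", "c", "d", "e")) {
      id <- paste0(num, letter)
      out[[id]] <- scenario_spec(
        id, base$hazards, weight_setting(letter),
        hr_nonfatal = base$hr_nonfatal, hr_fatal = base$hr_fatal,
        n_per_group = n_per_group, horizon = horizon,
        max_events = max_events)
    }
  }
  out
}

#' @rdname scenario_catalog
#' @export
get_scenario <- function(id, n_per_group = 100L, horizon = 3,
                         max_events = 100L) {
  m <- regmatches(id, regexec("^([0-9]+)([a-e])$", id))[[1L]]
  if (length(m) != 3L) stop("unknown scenario id: ", id)
  base <- scenario_base(m[2L])
  scenario_spec(id, base$hazards, weight_setting(m[3L]),
                hr_nonfatal = base$hr_nonfatal, hr_fatal = base$hr_fatal,
                n_per_group = n_per_group, horizon = horizon,
                max_events = max_events)
}

#' Serialize the scenario catalog to a YAML or JSON config
#'
#' Writes a plain-list description of the requested scenarios (hazard
#' shape and parameters per cause and group, weights, layout) so runs can
#' be driven from a config file.
#'
#' @param ids Character vector of scenario ids.
#' @param path Output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(ids, path) {
  specs <- lapply(ids, get_scenario)
  as_plain <- function(s) list(
    id = s$id,
    hazards = lapply(s$hazards, function(f)
      c(list(shape = f$shape, a = f$a), if (!is.null(f$b)) list(b = f$b))),
    weights = lapply(s$weights, function(w)
      list(method = w$method, w_fatal = w$w_fatal, w_nonfatal = w$w_nonfatal)),
    n_per_group = s$n_per_group, horizon = s$horizon,
    max_events = s$max_events)
  plain <- lapply(specs, as_plain)
  names(plain) <- ids
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required for YAML output")
    yaml::write_yaml(plain, path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("the 'jsonlite' package is required for JSON output")
    writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, pretty = TRUE), path)
  }
  invisible(path)
}
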