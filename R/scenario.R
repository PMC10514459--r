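#' Demographic events
#'
#' A scenario is a mainland source population plus an ordered list of timed
#' events. Times are years before present (larger = older, "present" = 0);
#' events must be strictly decreasing in time. Exactly one event founds the
#' island: `found_from_mainland` samples `capacity` individuals uniformly
#' without replacement from the mainland into a new island population (the
#' mainland persists). `set_capacity` changes a population's carrying
#' capacity instantaneously.
#'
#' @param time years before present (integer).
#' @param kind `"found_from_mainland"` or `"set_capacity"`.
#' @param population population label the event applies to.
#' @param capacity carrying capacity (also the number of founders for a
#'   founding event).
#' @return a `demographic_event`.
#' @export
demographic_event <- function(time, kind, population, capacity) {
  kind <- match.arg(kind, c("found_from_mainland", "set_capacity"))
  ev <- list(time = as.integer(time), kind = kind,
             population = as.character(population),
             capacity = as.numeric(capacity))
  if (ev$time < 0) stop("event time must be >= 0 (years before present)")
  if (ev$capacity < 2) stop("carrying_capacity must be >= 2")
  class(ev) <- "demographic_event"
  ev
}

#' Demographic scenario
#'
#' @param label scenario label.
#' @param events list of [demographic_event()]s, strictly decreasing in time.
#' @param mainland_capacity carrying capacity of the mainland source
#'   population (default 50,000).
#' @param burnin_years burn-in duration for the mainland before the oldest
#'   event (default 500,000).
#' @return an object of class `fs_scenario`.
#' @export
scenario <- function(label, events, mainland_capacity = 50000,
                     burnin_years = 500000) {
  sc <- list(label = as.character(label),
             mainland_capacity = as.numeric(mainland_capacity),
             burnin_years = as.numeric(burnin_years),
             events = events)
  validate_scenario(sc)
  class(sc) <- "fs_scenario"
  sc
}

validate_scenario <- function(sc) {
  fail <- character()
  if (!length(sc$events)) fail <- c(fail, "scenario has no events")
  bad <- !vapply(sc$events, inherits, logical(1), "demographic_event")
  if (any(bad)) fail <- c(fail, "events must be demographic_event objects")
  if (!length(fail)) {
    times <- vapply(sc$events, `[[`, numeric(1), "time")
    if (any(diff(times) >= 0))
      fail <- c(fail, "event times must be strictly decreasing")
    kinds <- vapply(sc$events, `[[`, character(1), "kind")
    if (sum(kinds == "found_from_mainland") != 1)
      fail <- c(fail, "scenario must contain exactly one found_from_mainland event")
    else if (kinds[1] != "found_from_mainland")
      fail <- c(fail, "the founding event must be the oldest event")
    caps <- vapply(sc$events, `[[`, numeric(1), "capacity")
    if (any(caps < 2)) fail <- c(fail, "carrying capacities must be >= 2")
  }
  if (!is.null(sc$burnin_years) && sc$burnin_years <= 0)
    fail <- c(fail, "burnin_years must be positive")
  if (sc$mainland_capacity < 2)
    fail <- c(fail, "mainland_capacity must be >= 2")
  if (length(fail))
    stop("invalid scenario: ", paste(fail, collapse = "; "))
  invisible(sc)
}

#' @export
print.fs_scenario <- function(x, ...) {
  cat("<scenario>", x$label, "\n")
  cat("  mainland K =", format(x$mainland_capacity, big.mark = ","),
      " burn-in =", format(x$burnin_years, big.mark = ","), "years\n")
  for (ev in x$events)
    cat(sprintf("  %6d BP  %-20s %-10s K = %s\n", ev$time, ev$kind,
                ev$population, format(ev$capacity, big.mark = ",")))
  invisible(x)
}

.scenario_keys <- c("label", "mainland_capacity", "burnin_years", "events")
.event_keys <- c("time", "kind", "population", "capacity")

#' Load a scenario from a YAML or JSON config file
#'
#' The config dialect mirrors the [scenario()] constructor: top-level keys
#' `label`, `mainland_capacity`, `burnin_years`, `events`; each event has
#' `time`, `kind`, `population`, `capacity`. Unknown keys are rejected and
#' every scenario invariant is checked.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a validated `fs_scenario`.
#' @seealso [write_scenario()], [scenario_library()]
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (!is.list(raw)) stop("malformed scenario file: ", path)
  extra <- setdiff(names(raw), .scenario_keys)
  if (length(extra))
    stop("unknown key(s) in scenario file: ", paste(extra, collapse = ", "))
  missing <- setdiff(c("label", "events"), names(raw))
  if (length(missing))
    stop("scenario file missing key(s): ", paste(missing, collapse = ", "))
  events <- lapply(raw$events, function(ev) {
    if (!is.list(ev)) stop("malformed event entry (key: events)")
    extra <- setdiff(names(ev), .event_keys)
    if (length(extra))
      stop("unknown key(s) in event: ", paste(extra, collapse = ", "))
    missing <- setdiff(.event_keys, names(ev))
    if (length(missing))
      stop("event missing key(s): ", paste(missing, collapse = ", "))
    demographic_event(ev$time, ev$kind, ev$population, ev$capacity)
  })
  scenario(raw$label, events,
           mainland_capacity = raw$mainland_capacity %||% 50000,
           burnin_years = raw$burnin_years %||% 500000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a scenario to YAML
#'
#' Round-trips losslessly through [load_scenario()].
#'
#' @param sc an `fs_scenario`.
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_scenario <- function(sc, path) {
  validate_scenario(sc)
  out <- list(label = sc$label,
              mainland_capacity = sc$mainland_capacity,
              burnin_years = sc$burnin_years,
              events = lapply(sc$events, function(ev)
                list(time = ev$time, kind = ev$kind,
                     population = ev$population, capacity = ev$capacity)))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Construct a founder/bottleneck/recovery scenario
#'
#' The standard island history: founding at 7,000 BP with
#' `founder_size` individuals, recovery to `recovery_size` at 6,900 BP,
#' increase to 20,000 at 1,200 BP, overharvest bottleneck to 1,800 at
#' 200 BP, and recovery to 20,000 at 100 BP.
#'
#' @param founder_size island founder carrying capacity (and founder count).
#' @param recovery_size post-colonisation carrying capacity.
#' @param label scenario label; default `founder<k>_rec<K>`.
#' @return an `fs_scenario`.
#' @export
founder_scenario <- function(founder_size, recovery_size = 2000,
                             label = NULL) {
  if (is.null(label))
    label <- sprintf("founder%d_rec%d", founder_size, recovery_size)
  scenario(label, list(
    demographic_event(7000, "found_from_mainland", "island", founder_size),
    demographic_event(6900, "set_capacity", "island", recovery_size),
    demographic_event(1200, "set_capacity", "island", 20000),
    demographic_event(200, "set_capacity", "island", 1800),
    demographic_event(100, "set_capacity", "island", 20000)
  ))
}

#' Null scenario: large, stable island with only the recent bottleneck
#'
#' @return an `fs_scenario` founded with 20,000 individuals at 7,000 BP,
#'   with the 200 BP bottleneck and 100 BP recovery.
#' @export
null_scenario <- function() {
  scenario("null_K20000", list(
    demographic_event(7000, "found_from_mainland", "island", 20000),
    demographic_event(200, "set_capacity", "island", 1800),
    demographic_event(100, "set_capacity", "island", 20000)
  ))
}

#' The shipped scenario library
#'
#' All founder-size x recovery-size combinations (founder 25, 50, 100, 250,
#' 500; recovery 1,000, 2,000, 5,000) plus the null scenario.
#'
#' @return named list of `fs_scenario` objects.
#' @export
scenario_library <- function() {
  out <- list()
  for (f in c(25, 50, 100, 250, 500))
    for (r in c(1000, 2000, 5000)) {
      sc <- founder_scenario(f, r)
      out[[sc$label]] <- sc
    }
  out[["null_K20000"]] <- null_scenario()
  out
}
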