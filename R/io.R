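#' Build an event log of meals and insulin records
#'
#' The event log is a tibble with one row per self-reported or pump event:
#' `time` (POSIXct), `kind` (`"meal"`, `"bolus"` or `"basal"`), `amount`
#' (grams of carbohydrate for meals, IU for boluses, IU/h for basal rate
#' changes; `NA` allowed for meals with unknown size) and a free-text
#' `label`. Timestamps must be sorted ascending within each kind and
#' amounts, when present, non-negative.
#'
#' @param time POSIXct event times.
#' @param kind character vector in `{"meal","bolus","basal"}`.
#' @param amount numeric amounts (see above), `NA` allowed for meals.
#' @param label optional free-text labels (e.g. "breakfast",
#'   "hypo_treatment").
#' @return A tibble of class `event_log`.
#' @export
event_log <- function(time = as.POSIXct(character(), tz = "UTC"),
                      kind = character(), amount = double(),
                      label = character()) {
  n <- length(time)
  if (length(kind) != n) abort("`time` and `kind` must have equal length.")
  if (length(amount) == 0 && n > 0) amount <- rep(NA_real_, n)
  if (length(label) == 0 && n > 0) label <- rep(NA_character_, n)
  bad_kind <- setdiff(unique(kind), c("meal", "bolus", "basal"))
  if (length(bad_kind) > 0) {
    abort(sprintf("Unknown event kind(s): %s.", paste(bad_kind, collapse = ", ")))
  }
  if (any(!is.na(amount) & amount < 0)) {
    abort("Event amounts must be non-negative.")
  }
  out <- tibble::tibble(time = time, kind = kind,
                        amount = as.double(amount), label = as.character(label))
  out <- out[order(out$time), , drop = FALSE]
  for (k in unique(out$kind)) {
    tk <- out$time[out$kind == k]
    if (is.unsorted(tk)) abort(sprintf("%s timestamps are not sorted.", k))
  }
  class(out) <- c("event_log", class(out))
  out
}

#' Convenience accessor: the meal rows of an event log
#'
#' @param events an [event_log()].
#' @param include_hypo_treatments if `FALSE`, meals labelled
#'   `"hypo_treatment"` (hypoglycemia rescue carbohydrates, present in the
#'   meal lists of pump datasets) are dropped; by default they count as
#'   meals and anchor postprandial periods.
#' @return A tibble of meal events.
#' @export
meal_events <- function(events, include_hypo_treatments = TRUE) {
  m <- events[events$kind == "meal", , drop = FALSE]
  if (!include_hypo_treatments) {
    m <- m[is.na(m$label) | m$label != "hypo_treatment", , drop = FALSE]
  }
  m
}

#' Read a CGM trace from CSV onto the uniform 5-minute grid
#'
#' Expects a header `timestamp,glucose_mg_dl` with ISO-8601 timestamps and an
#' empty glucose field for missing readings. Raw timestamps are snapped to
#' the nearest slot of a 5-minute grid anchored at midnight of the first day
#' (ties snap to the earlier slot, an arbitrary but fixed convention for
#' drifting sensor clocks); duplicate slots keep the last record; grid slots
#' covered by no record are marked missing.
#'
#' @param path CSV file path.
#' @param sampling_minutes grid spacing in minutes.
#' @return A [glucose_series()].
#' @export
read_cgm_csv <- function(path, sampling_minutes = 5) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_datetime(),
    glucose_mg_dl = readr::col_double()
  ), progress = FALSE))
  pb <- readr::problems(raw)
  if (nrow(pb) > 0) {
    abort(sprintf("Malformed CGM CSV at line %d: %s", pb$row[1] + 1L, pb$expected[1]))
  }
  if (anyNA(raw$timestamp)) {
    abort(sprintf("Malformed CGM CSV: unparseable timestamp at data row %d.",
                  which(is.na(raw$timestamp))[1]))
  }
  if (is.unsorted(raw$timestamp)) {
    abort("CGM timestamps must be non-decreasing.")
  }
  series_from_samples(raw$timestamp, raw$glucose_mg_dl, sampling_minutes)
}

# Snap irregular samples onto the uniform grid; shared by the CSV and XML
# readers and by the simulator round trip.
series_from_samples <- function(times, values, sampling_minutes = 5) {
  if (length(times) == 0) abort("No CGM samples.")
  step_sec <- sampling_minutes * 60
  origin <- as.POSIXct(trunc(min(times), units = "days"), tz = "UTC")
  slot <- snap_to_grid(times, origin, step_sec)
  first <- min(slot)
  last <- max(slot)
  glucose <- rep(NA_real_, last - first + 1L)
  # keep the last record for a duplicated slot
  glucose[slot - first + 1L] <- values
  time <- origin + (first:last) * step_sec
  glucose_series(time, glucose, sampling_minutes)
}

#' Read a meal/insulin event log from CSV
#'
#' Expects a header `timestamp,kind,amount,label` with `kind` in
#' `{meal, bolus, basal}`; `amount` is grams for meals (may be empty), IU
#' for boluses, IU/h for basal rate changes.
#'
#' @param path CSV file path.
#' @return An [event_log()].
#' @export
read_events_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    timestamp = readr::col_datetime(),
    kind = readr::col_character(),
    amount = readr::col_double(),
    label = readr::col_character()
  ), progress = FALSE))
  pb <- readr::problems(raw)
  if (nrow(pb) > 0) {
    abort(sprintf("Malformed events CSV at line %d: %s", pb$row[1] + 1L, pb$expected[1]))
  }
  event_log(raw$timestamp, raw$kind, raw$amount, raw$label)
}

#' Read the OhioT1DM XML layout
#'
#' Parses the per-subject XML files of the OhioT1DM dataset (which is
#' access-restricted and therefore never shipped with this package) into the
#' same pair of structures the CSV readers produce: `<glucose_level>` events
#' become a [glucose_series()], and `<meal>`, `<bolus>` and `<basal>` events
#' an [event_log()].
#'
#' @param path XML file path.
#' @param sampling_minutes grid spacing in minutes.
#' @return A list with elements `series` and `events`.
#' @export
read_ohio_xml <- function(path, sampling_minutes = 5) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  doc <- xml2::read_xml(path)
  parse_ts <- function(x) {
    out <- as.POSIXct(x, tz = "UTC", format = "%d-%m-%Y %H:%M:%S")
    iso <- is.na(out)
    if (any(iso)) out[iso] <- as.POSIXct(x[iso], tz = "UTC")
    if (anyNA(out)) abort("Unparseable timestamp in OhioT1DM XML.")
    out
  }
  grab <- function(section, ts_attr, val_attr) {
    nodes <- xml2::xml_find_all(doc, sprintf(".//%s/event", section))
    if (length(nodes) == 0) {
      return(tibble::tibble(time = as.POSIXct(character(), tz = "UTC"),
                            value = double(), label = character()))
    }
    ts <- xml2::xml_attr(nodes, ts_attr)
    if (all(is.na(ts)) && ts_attr != "ts") ts <- xml2::xml_attr(nodes, "ts")
    val <- suppressWarnings(as.double(xml2::xml_attr(nodes, val_attr)))
    lab <- xml2::xml_attr(nodes, "type")
    tibble::tibble(time = parse_ts(ts), value = val, label = lab)
  }
  gl <- grab("glucose_level", "ts", "value")
  if (nrow(gl) == 0) abort("OhioT1DM XML contains no <glucose_level> events.")
  o <- order(gl$time)
  series <- series_from_samples(gl$time[o], gl$value[o], sampling_minutes)
  meals <- grab("meal", "ts", "carbs")
  boluses <- grab("bolus", "ts_begin", "dose")
  basal <- grab("basal", "ts", "value")
  events <- event_log(
    time = c(meals$time, boluses$time, basal$time),
    kind = rep(c("meal", "bolus", "basal"), c(nrow(meals), nrow(boluses), nrow(basal))),
    amount = c(meals$value, boluses$value, basal$value),
    label = c(meals$label, rep(NA_character_, nrow(boluses) + nrow(basal)))
  )
  list(series = series, events = events)
}

#' Write a CGM series / event log back to the canonical CSV layouts
#'
#' @param series a [glucose_series()].
#' @param events an [event_log()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cgm_csv <- function(series, path) {
  readr::write_csv(
    tibble::tibble(timestamp = format(series$time, "%Y-%m-%dT%H:%M:%SZ"),
                   glucose_mg_dl = series$glucose),
    path, na = ""
  )
  invisible(path)
}

#' @rdname write_cgm_csv
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(
    tibble::tibble(timestamp = format(events$time, "%Y-%m-%dT%H:%M:%SZ"),
                   kind = events$kind, amount = events$amount, label = events$label),
    path, na = ""
  )
  invisible(path)
}
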