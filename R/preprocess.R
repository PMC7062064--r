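#' Construct a per-individual event sequence
#'
#' Holds the sorted event start times of one individual together with the
#' recording metadata needed for preprocessing: the time resolution (smallest
#' possible spacing between distinct events, e.g. 20 s for proximity-sensor
#' data) and the day length / day origin used to decide whether two
#' consecutive events fall on different days.
#'
#' @param individual_id identifier of the individual (any scalar).
#' @param timestamps numeric vector of event start times; sorted internally.
#' @param resolution smallest time step of the recording, in the same unit as
#'   `timestamps`. Must be positive.
#' @param day_length duration of one day in the same unit (default 86400 s).
#' @param day_origin offset of the first day boundary (default 0). An event at
#'   time t belongs to day `floor((t - day_origin) / day_length)`.
#' @param unit time unit label, metadata only.
#' @return an object of class `event_sequence`.
#' @export
event_sequence <- function(individual_id, timestamps, resolution,
                           day_length = 86400, day_origin = 0,
                           unit = "seconds") {
  stopifnot(is.numeric(timestamps), length(resolution) == 1L, resolution > 0,
            length(day_length) == 1L, day_length > 0)
  if (anyNA(timestamps)) stop("timestamps contain NA")
  structure(list(individual_id = individual_id,
                 timestamps = sort(as.numeric(timestamps)),
                 resolution = as.numeric(resolution),
                 day_length = as.numeric(day_length),
                 day_origin = as.numeric(day_origin),
                 unit = unit),
            class = "event_sequence")
}

#' @export
print.event_sequence <- function(x, ...) {
  cat(sprintf("Event sequence for individual %s: %d events (%s), resolution %g\n",
              format(x$individual_id), length(x$timestamps), x$unit,
              x$resolution))
  invisible(x)
}

#' Construct an inter-event-time sequence
#'
#' An ordered multiset of strictly positive durations between consecutive
#' events of one individual.
#'
#' @param values numeric vector of strictly positive inter-event times.
#' @param unit time unit label ("seconds" or "days"), metadata only.
#' @param individual_id optional identifier carried along from the source
#'   event sequence.
#' @return an object of class `iet`, with `$values`, `$n` and `$unit`.
#' @export
iet <- function(values, unit = "seconds", individual_id = NULL) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("inter-event times contain NA")
  if (any(values <= 0)) {
    stop("inter-event times must be strictly positive; zero gaps usually mean ",
         "simultaneous events were not merged (see events_to_iets flags)")
  }
  structure(list(values = values, n = length(values), unit = unit,
                 individual_id = individual_id),
            class = "iet")
}

#' @export
print.iet <- function(x, ...) {
  cat(sprintf("%d inter-event times (%s)", x$n, x$unit))
  if (x$n > 0)
    cat(sprintf("; range [%g, %g], mean %g", min(x$values), max(x$values),
                mean(x$values)))
  cat("\n")
  invisible(x)
}

#' @export
length.iet <- function(x) x$n

# Accept either an iet object or a bare numeric vector of durations.
iet_values <- function(tau) {
  if (inherits(tau, "iet")) return(tau$values)
  v <- as.numeric(tau)
  if (any(v <= 0)) stop("inter-event times must be strictly positive")
  v
}

#' Convert an event sequence into inter-event times
#'
#' Applies the standard preprocessing rules for sensor-derived contact data:
#' events recorded at the same time are aggregated into one event; runs of
#' events in consecutive resolution-sized time windows (spacing exactly equal
#' to the resolution) are collapsed to their first event, so that one long
#' contact is not counted as many short ones; and gaps whose two endpoint
#' events fall on different days can be excluded, which removes overnight
#' gaps dominated by the circadian rhythm rather than by the individual's
#' event dynamics.  With the run-merging rule active the minimum possible
#' inter-event time equals the resolution.
#'
#' @param events an [event_sequence].
#' @param merge_consecutive collapse runs of events at spacing exactly equal
#'   to the resolution to their first event (default TRUE).
#' @param merge_simultaneous aggregate events with identical timestamps
#'   (default TRUE).
#' @param exclude_cross_day drop gaps spanning a day boundary (default FALSE).
#' @return an [iet] object. The retained event times are available in
#'   attribute `"retained"`, and the number of dropped cross-day gaps in
#'   attribute `"dropped_cross_day"`.
#' @export
events_to_iets <- function(events, merge_consecutive = TRUE,
                           merge_simultaneous = TRUE,
                           exclude_cross_day = FALSE) {
  stopifnot(inherits(events, "event_sequence"))
  ts <- events$timestamps
  if (is.unsorted(ts)) stop("event timestamps must be non-decreasing")
  if (merge_simultaneous) ts <- unique(ts)
  if (merge_consecutive && length(ts) > 1L) {
    d <- diff(ts)
    eps <- 1e-9 * max(1, events$resolution)
    # an event starting exactly one resolution step after the previous
    # retained-or-merged event continues the same run
    keep <- logical(length(ts))
    keep[1L] <- TRUE
    for (i in 2L:length(ts)) {
      keep[i] <- abs(d[i - 1L] - events$resolution) > eps
    }
    ts <- ts[keep]
  }
  if (length(ts) < 2L) {
    out <- iet(numeric(0), unit = events$unit,
               individual_id = events$individual_id)
    attr(out, "retained") <- ts
    attr(out, "dropped_cross_day") <- 0L
    return(out)
  }
  gaps <- diff(ts)
  if (any(gaps < 0)) stop("negative timestamp differences")
  dropped <- 0L
  if (exclude_cross_day) {
    day <- floor((ts - events$day_origin) / events$day_length)
    same_day <- diff(day) == 0
    dropped <- sum(!same_day)
    gaps <- gaps[same_day]
  }
  out <- iet(gaps, unit = events$unit, individual_id = events$individual_id)
  attr(out, "retained") <- ts
  attr(out, "dropped_cross_day") <- dropped
  out
}

#' Filter individuals by number of inter-event times
#'
#' Keeps the individuals whose IET sequence has at least `min_n` entries
#' (e.g. at least 100 for most datasets, 50 for sparse ones), preserving
#' order.
#'
#' @param iets a list of [iet] objects.
#' @param min_n minimum number of inter-event times (>= 1).
#' @return the filtered list.
#' @export
filter_individuals <- function(iets, min_n) {
  stopifnot(min_n >= 1)
  iets[vapply(iets, function(x) x$n >= min_n, logical(1))]
}

#' Read a raw event file
#'
#' One event per line, whitespace- or comma-delimited:
#' `individual_id timestamp [partner_id]`. Lines starting with `#` are
#' ignored.  For undirected contact data each event with a partner column is
#' attributed to both endpoints; for directed records only the first column
#' (the sender) receives the event.
#'
#' @param path file path.
#' @param directed logical; if TRUE events are attributed to senders only.
#' @param resolution,day_length,day_origin,unit passed to [event_sequence].
#' @return a named list of [event_sequence] objects, one per individual.
#' @export
read_events <- function(path, directed = FALSE, resolution,
                        day_length = 86400, day_origin = 0,
                        unit = "seconds") {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  by_id <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[[i]]), "[,[:space:]]+")[[1]]
    if (length(f) < 2L)
      stop(sprintf("malformed event line %d: '%s'", i, lines[[i]]))
    t <- suppressWarnings(as.numeric(f[2L]))
    if (is.na(t))
      stop(sprintf("malformed event line %d: non-numeric timestamp '%s'",
                   i, f[2L]))
    ids <- f[1L]
    if (!directed && length(f) >= 3L) ids <- c(ids, f[3L])
    for (id in ids) by_id[[id]] <- c(by_id[[id]], t)
  }
  lapply(setNames(names(by_id), names(by_id)), function(id)
    event_sequence(id, by_id[[id]], resolution = resolution,
                   day_length = day_length, day_origin = day_origin,
                   unit = unit))
}

#' Read a pre-computed inter-event-time file
#'
#' One strictly positive duration per line; `#` comment lines ignored.
#'
#' @param path file path.
#' @param unit time unit label.
#' @return an [iet] object.
#' @export
read_iets <- function(path, unit = "seconds") {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  v <- suppressWarnings(as.numeric(lines))
  if (anyNA(v)) stop("non-numeric line in IET file ", path)
  iet(v, unit = unit)
}

#' Write inter-event times with a JSON sidecar
#'
#' Writes one value per line to `path` and a `<path>.json` sidecar recording
#' n, the unit and any preprocessing flags supplied.
#'
#' @param x an [iet] object.
#' @param path output file path.
#' @param flags optional named list recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_iets <- function(x, path, flags = list()) {
  stopifnot(inherits(x, "iet"))
  writeLines(format(x$values, scientific = FALSE, trim = TRUE), path)
  meta <- c(list(n = x$n, unit = x$unit,
                 individual_id = x$individual_id), flags)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
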