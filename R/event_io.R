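#' A single nanopore translocation event
#'
#' One current-blockade event: the transient dip in ionic current while a single
#' molecule passes the pore, as a variable-length numeric trace (relative
#' blockade, arbitrary units) plus a class label and provenance metadata.
#'
#' @param id Unique event identifier.
#' @param trace Numeric vector of finite values, length >= 1.
#' @param label Class name; empty string for unlabeled events.
#' @param source Free-text provenance (e.g. pore id).
#' @param duration_points Raw event length in sampling points before any
#'   resampling; defaults to `length(trace)`.
#' @return An object of class `event_record`.
#' @export
event_record <- function(id, trace, label = "", source = "",
                         duration_points = length(trace)) {
  id <- as.character(id)
  trace <- as.numeric(trace)
  if (length(id) != 1L || !nzchar(id)) stopf("event_record: 'id' must be a single non-empty string")
  if (length(trace) < 1L) stopf("event_record: trace of '%s' is empty", id)
  if (any(!is.finite(trace))) stopf("event_record: non-finite value in trace of '%s'", id)
  if (!is_count(duration_points)) stopf("event_record: 'duration_points' of '%s' must be >= 1", id)
  structure(list(id = id, trace = trace, label = as.character(label),
                 source = as.character(source),
                 duration_points = as.integer(duration_points)),
            class = "event_record")
}

#' An ordered collection of events
#'
#' Container for a dataset of [event_record]s. `class_names` lists every
#' non-empty label in order of first appearance; `fixed_length` is set once all
#' traces share one length (always after preprocessing, see
#' [preprocess_events()]).
#'
#' @param events List of [event_record] objects.
#' @param fixed_length Optional integer; when given, every trace must have
#'   exactly this length. When `NULL` it is inferred if all traces happen to
#'   share one length.
#' @return An object of class `event_set`.
#' @export
event_set <- function(events, fixed_length = NULL) {
  if (!is.list(events)) stopf("event_set: 'events' must be a list")
  for (e in events) if (!inherits(e, "event_record"))
    stopf("event_set: all elements must be event_record objects")
  ids <- vapply(events, `[[`, "", "id")
  dup <- anyDuplicated(ids)
  if (dup) stopf("event_set: duplicate id '%s'", ids[dup])
  labs <- vapply(events, `[[`, "", "label")
  class_names <- unique(labs[nzchar(labs)])
  lens <- lengths(lapply(events, `[[`, "trace"))
  if (!is.null(fixed_length)) {
    fixed_length <- as.integer(fixed_length)
    if (length(events) && any(lens != fixed_length))
      stopf("event_set: fixed_length = %d but traces of other lengths present", fixed_length)
  } else if (length(events) && length(unique(lens)) == 1L) {
    fixed_length <- as.integer(lens[1L])
  }
  structure(list(events = events, class_names = class_names,
                 fixed_length = fixed_length),
            class = "event_set")
}

#' @export
length.event_set <- function(x) length(x$events)

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("<event_set> %d events, %d classes%s\n", length(x$events),
              length(x$class_names),
              if (is.null(x$fixed_length)) " (variable length)"
              else sprintf(", fixed length %d", x$fixed_length)))
  invisible(x)
}

#' Event-set accessors
#'
#' `event_labels()` and `event_ids()` return the per-event label/id vectors;
#' `subset_events()` takes an integer-indexed subset, preserving order and the
#' fixed-length contract.
#'
#' @param set An [event_set].
#' @param idx Integer indices into the set.
#' @return Character vector (`event_labels`, `event_ids`) or an [event_set]
#'   (`subset_events`).
#' @export
event_labels <- function(set) vapply(set$events, `[[`, "", "label")

#' @rdname event_labels
#' @export
event_ids <- function(set) vapply(set$events, `[[`, "", "id")

#' @rdname event_labels
#' @export
subset_events <- function(set, idx) {
  event_set(set$events[idx], fixed_length = set$fixed_length)
}

#' Read an event dataset from disk
#'
#' Two plain-text dialects are supported. `ndjson`: one JSON object per line
#' with keys `id` (string), `trace` (number array), `label` (string, optional,
#' default `""`), `source` (string, optional) and `duration_points` (integer,
#' optional, default the trace length) — the canonical format, since raw events
#' are variable-length. `matrix_tsv`: a rectangular dialect for fixed-length
#' sets, header `id<TAB>label<TAB>t0...t{F-1}`, one event per row;
#' `fixed_length` is set to the trace column count.
#'
#' @param path File to read.
#' @param format `"ndjson"` or `"matrix_tsv"`.
#' @return An [event_set], preserving record order and labels verbatim.
#' @export
read_events <- function(path, format = c("ndjson", "matrix_tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("read_events: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (format == "ndjson") {
    events <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                      error = function(e) NULL)
      if (is.null(rec) || !is.list(rec))
        stopf("read_events: malformed JSON at line %d", i)
      if (is.null(rec$id)) stopf("read_events: missing 'id' at line %d", i)
      if (is.null(rec$trace)) stopf("read_events: missing 'trace' at line %d", i)
      tr <- as.numeric(rec$trace)
      if (length(tr) < 1L || any(!is.finite(tr)))
        stopf("read_events: non-finite or empty trace in record '%s' (line %d)", rec$id, i)
      events[[i]] <- event_record(
        id = rec$id, trace = tr,
        label = if (is.null(rec$label)) "" else rec$label,
        source = if (is.null(rec$source)) "" else rec$source,
        duration_points = if (is.null(rec$duration_points)) length(tr)
                          else rec$duration_points)
    }
    event_set(events)
  } else {
    if (!length(lines)) stopf("read_events: empty matrix_tsv file (missing header)")
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 3L || header[1L] != "id" || header[2L] != "label")
      stopf("read_events: malformed matrix_tsv header at line 1")
    F_len <- length(header) - 2L
    events <- vector("list", length(lines) - 1L)
    for (i in seq_along(events)) {
      fields <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
      if (length(fields) != F_len + 2L)
        stopf("read_events: row of wrong width at line %d", i + 1L)
      tr <- suppressWarnings(as.numeric(fields[-(1:2)]))
      if (any(!is.finite(tr)))
        stopf("read_events: non-finite value in record '%s' (line %d)", fields[1L], i + 1L)
      events[[i]] <- event_record(id = fields[1L], trace = tr, label = fields[2L],
                                  duration_points = F_len)
    }
    event_set(events, fixed_length = F_len)
  }
}

#' Write an event dataset to disk
#'
#' Inverse of [read_events()]: numbers are serialized with 17 significant
#' digits, so `read_events(write_events(x))` reproduces every trace value
#' exactly. `matrix_tsv` requires a fixed-length set.
#'
#' @param set An [event_set].
#' @param path Output file.
#' @param format `"ndjson"` or `"matrix_tsv"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(set, path, format = c("ndjson", "matrix_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(set, "event_set"))
  if (format == "ndjson") {
    lines <- vapply(set$events, function(e) {
      jsonlite::toJSON(list(id = e$id, trace = I(e$trace), label = e$label,
                            source = e$source,
                            duration_points = e$duration_points),
                       auto_unbox = TRUE, digits = NA)
    }, "")
  } else {
    if (is.null(set$fixed_length))
      stopf("write_events: matrix_tsv requires a fixed-length event_set")
    F_len <- set$fixed_length
    header <- paste(c("id", "label", sprintf("t%d", seq_len(F_len) - 1L)),
                    collapse = "\t")
    rows <- vapply(set$events, function(e) {
      paste(c(e$id, e$label, sprintf("%.17g", e$trace)), collapse = "\t")
    }, "")
    lines <- c(header, rows)
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("write_events: cannot write to '%s'", path)
  invisible(path)
}
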