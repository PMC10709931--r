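#' Read a participant's CGM and event files
#'
#' The CGM file has header `timestamp,glucose_mg_dl` with ISO-8601 UTC
#' timestamps, one row per reading; absent rows are gaps. The events file has
#' header `timestamp,event_type`. Events are returned unsynchronized (no grid
#' indices); patterns and profiles are empty.
#'
#' @param cgmPath path to the CGM CSV.
#' @param eventsPath path to the events CSV.
#' @param participantId identifier; defaults to the CGM file name sans
#'   extension.
#' @param interval grid spacing in minutes.
#' @return A [ParticipantData-class] with empty patterns and profiles.
#' @export
readParticipant <- function(cgmPath, eventsPath,
                            participantId = sub("\\.[^.]*$", "",
                                                basename(cgmPath)),
                            interval = 5) {
  gs <- readGlucoseCSV(cgmPath, participantId = participantId,
                       interval = interval)
  ev <- readEventsCSV(eventsPath)
  new("ParticipantData", id = participantId, glucose = gs, events = ev,
      patterns = list(), profiles = list())
}

.parseTimes <- function(raw, path) {
  t <- as.POSIXct(raw, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                 "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  bad <- which(is.na(t))
  if (length(bad))
    stop("malformed timestamp in ", path, " at data row ", bad[1],
         " (line ", bad[1] + 1L, "): '", raw[bad[1]], "'")
  t
}

#' @rdname readParticipant
#' @param path CSV path.
#' @export
readGlucoseCSV <- function(path, participantId = "anon", interval = 5) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("timestamp", "glucose_mg_dl") %in% names(df)))
    stop("CGM file ", path, " must have header timestamp,glucose_mg_dl")
  if (nrow(df) == 0L)
    return(glucoseSeries(as.POSIXct(character(), tz = "UTC"), numeric(),
                         participantId, interval))
  t <- .parseTimes(df$timestamp, path)
  g <- suppressWarnings(as.numeric(df$glucose_mg_dl))
  bad <- which(is.na(g))
  if (length(bad))
    stop("malformed glucose value in ", path, " at data row ", bad[1],
         " (line ", bad[1] + 1L, "): '", df$glucose_mg_dl[bad[1]], "'")
  bad <- which(!is.finite(g) | g <= 0)
  if (length(bad))
    stop("out-of-range glucose (must be finite, > 0 mg/dl) in ", path,
         " at data row ", bad[1], " (line ", bad[1] + 1L, ")")
  if (is.unsorted(as.numeric(t), strictly = TRUE))
    stop("timestamps in ", path, " must be strictly increasing")
  glucoseSeries(t, g, participantId, interval)
}

#' @rdname readParticipant
#' @export
readEventsCSV <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("timestamp", "event_type") %in% names(df)))
    stop("events file ", path, " must have header timestamp,event_type")
  if (nrow(df) == 0L) return(eventLog())
  t <- .parseTimes(df$timestamp, path)
  bad <- which(!(df$event_type %in% .EVENT_TYPES))
  if (length(bad))
    stop("unknown event_type in ", path, " at data row ", bad[1],
         " (line ", bad[1] + 1L, "): '", df$event_type[bad[1]], "'")
  if (is.unsorted(as.numeric(t)))
    stop("event timestamps in ", path, " must be non-decreasing")
  eventLog(t, df$event_type)
}

.fmtTime <- function(t) format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Write a GlucoseSeries or EventLog back to CSV
#'
#' Inverse of the readers: gaps become absent rows, timestamps are written as
#' ISO-8601 UTC, so a write/read round trip reproduces the object exactly.
#'
#' @param x the object to write.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeGlucoseCSV <- function(x, path) {
  keep <- !is.na(x@values)
  df <- data.frame(timestamp = .fmtTime(gridTimes(x)[keep]),
                   glucose_mg_dl = sprintf("%.17g", x@values[keep]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGlucoseCSV
#' @export
writeEventsCSV <- function(x, path) {
  df <- data.frame(timestamp = .fmtTime(eventTimes(x)),
                   event_type = eventTypes(x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
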