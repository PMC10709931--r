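#' Construct a GlucoseSeries from timestamped readings
#'
#' Readings are snapped onto the grid defined by the first timestamp and
#' `interval`: a reading more than `interval / 2` minutes off-grid is moved to
#' the nearest grid position; when two readings snap to the same position the
#' first is kept (with a warning). Grid positions without a reading become
#' gaps (`NA`).
#'
#' @param times `POSIXct` timestamps, strictly increasing.
#' @param glucose numeric glucose readings, mg/dl, finite and positive.
#' @param participantId identifier string.
#' @param interval grid spacing in minutes (default 5).
#' @return A [GlucoseSeries-class].
#' @examples
#' t0 <- as.POSIXct("2023-04-01 08:00:00", tz = "UTC")
#' gs <- glucoseSeries(t0 + c(0, 300, 900), c(110, 115, 140))
#' seriesLength(gs)       # 4 grid positions, one gap at 08:10
#' @export
glucoseSeries <- function(times, glucose, participantId = "anon",
                          interval = 5) {
  if (length(times) != length(glucose))
    stop("times and glucose must have the same length")
  if (length(times) == 0L) {
    return(new("GlucoseSeries", participantId = participantId,
               interval = interval,
               startTime = as.POSIXct(numeric(0), origin = "1970-01-01",
                                      tz = "UTC")[1],
               values = numeric(0)))
  }
  if (is.unsorted(as.numeric(times), strictly = TRUE))
    stop("timestamps must be strictly increasing")
  step <- interval * 60
  off <- as.numeric(times) - as.numeric(times[1])
  idx <- as.integer(round(off / step)) + 1L
  if (anyDuplicated(idx)) {
    warning("duplicate readings after grid snapping; keeping the first")
    keep <- !duplicated(idx)
    idx <- idx[keep]
    glucose <- glucose[keep]
  }
  m <- max(idx)
  values <- rep(NA_real_, m)
  values[idx] <- glucose
  new("GlucoseSeries", participantId = participantId, interval = interval,
      startTime = as.POSIXct(times[1], tz = "UTC"), values = values)
}

#' Construct an EventLog
#'
#' @param times `POSIXct` event timestamps, non-decreasing.
#' @param types event types from
#'   `breakfast, lunch, dinner, snack, hypo_correction`.
#' @param gridIndex optional synchronized grid indices (`NA` before
#'   [synchronizeEvents()]).
#' @return An [EventLog-class].
#' @export
eventLog <- function(times = as.POSIXct(character(), tz = "UTC"),
                     types = character(),
                     gridIndex = rep(NA_integer_, length(times))) {
  new("EventLog", times = as.POSIXct(times, tz = "UTC"),
      types = as.character(types), gridIndex = as.integer(gridIndex))
}

#' @rdname glucoseSeries
#' @param x a `GlucoseSeries`.
#' @export
seriesLength <- function(x) length(x@values)

#' Grid timestamps of a GlucoseSeries
#'
#' @param x a [GlucoseSeries-class].
#' @return `POSIXct` vector of length `seriesLength(x)` covering every grid
#'   position, including gaps.
#' @export
gridTimes <- function(x) {
  m <- seriesLength(x)
  x@startTime + (seq_len(m) - 1) * x@interval * 60
}

#' @rdname gridTimes
#' @export
seriesValues <- function(x) x@values

#' @rdname gridTimes
#' @export
seriesInterval <- function(x) x@interval

#' Logical gap mask of a GlucoseSeries
#'
#' @param x a [GlucoseSeries-class].
#' @return logical vector; `TRUE` where the grid position has no reading.
#' @export
isGap <- function(x) is.na(x@values)

#' @rdname eventLog
#' @param x an `EventLog`.
#' @export
nEvents <- function(x) length(x@times)

#' @rdname eventLog
#' @export
eventTimes <- function(x) x@times

#' @rdname eventLog
#' @export
eventTypes <- function(x) x@types

#' @rdname eventLog
#' @export
eventGridIndex <- function(x) x@gridIndex

setMethod("show", "GlucoseSeries", function(object) {
  m <- seriesLength(object)
  cat("GlucoseSeries '", object@participantId, "': ", m, " grid positions @ ",
      object@interval, " min (", sum(is.na(object@values)), " gaps)\n",
      sep = "")
  if (m > 0)
    cat("  span: ", format(object@startTime, "%Y-%m-%d %H:%M"), " .. ",
        format(object@startTime + (m - 1) * object@interval * 60,
               "%Y-%m-%d %H:%M"), " UTC\n", sep = "")
})

setMethod("show", "EventLog", function(object) {
  cat("EventLog: ", nEvents(object), " events",
      if (any(!is.na(object@gridIndex))) " (synchronized)" else "",
      "\n", sep = "")
  if (nEvents(object) > 0) {
    tab <- table(object@types)
    cat("  ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n",
        sep = "")
  }
})

setMethod("show", "ParticipantData", function(object) {
  cat("ParticipantData '", object@id, "'\n", sep = "")
  show(object@glucose)
  show(object@events)
  cat("  patterns: ", length(object@patterns),
      "   profiles: ", length(object@profiles), "\n", sep = "")
})

setMethod("show", "DistanceProfile", function(object) {
  fin <- object@values[is.finite(object@values)]
  cat("DistanceProfile (pattern ", object@patternId, ", n = ", object@n,
      "): length ", length(object@values), ", ",
      length(fin), " finite", sep = "")
  if (length(fin)) cat(", min ", round(min(fin), 3), sep = "")
  cat("\n")
})

setMethod("show", "ResponsePattern", function(object) {
  cat("ResponsePattern ", object@patternId, ": n = ",
      length(object@values), ", cluster size ",
      length(object@provenance), "\n", sep = "")
})

#' Extract a contiguous window from a GlucoseSeries
#'
#' Returns the window of `n` samples starting at grid position `i`
#' (positions `i .. i+n-1`), or `NULL` when any position in the window is a
#' gap — a window with a missing sample is not a valid response subsequence.
#'
#' @param x a [GlucoseSeries-class].
#' @param i 1-based start index, `1 <= i <= seriesLength(x) - n + 1`.
#' @param n window length in samples.
#' @return A [Subsequence-class], or `NULL` if the window crosses a gap.
#' @export
subsequenceAt <- function(x, i, n) {
  m <- seriesLength(x)
  if (n < 1L || n > m) stop("n must be in [1, m]")
  if (i < 1L || i > m - n + 1L)
    stop("start index ", i, " out of range [1, ", m - n + 1L, "]")
  v <- x@values[i:(i + n - 1L)]
  if (anyNA(v)) return(NULL)
  new("Subsequence", startIndex = as.integer(i), values = v)
}
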