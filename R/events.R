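#' Synchronize logged events to the glucose grid
#'
#' Each event is assigned the grid index of the nearest *existing* glucose
#' reading (gaps are skipped over); equidistant neighbors resolve to the
#' earlier reading. Events lying more than one grid interval outside the
#' series' time span are dropped with a warning.
#'
#' @param glucose a [GlucoseSeries-class], non-empty.
#' @param events an [EventLog-class].
#' @return The event log with `gridIndex` filled in (dropped events removed).
#' @export
synchronizeEvents <- function(glucose, events) {
  m <- seriesLength(glucose)
  if (m == 0L) stop("cannot synchronize against an empty GlucoseSeries")
  if (nEvents(events) == 0L) return(events)
  present <- which(!is.na(glucose@values))
  if (length(present) == 0L)
    stop("glucose series has no readings (all gaps)")
  gt <- as.numeric(gridTimes(glucose))[present]
  step <- glucose@interval * 60
  et <- as.numeric(eventTimes(events))
  lo <- as.numeric(glucose@startTime) - step
  hi <- as.numeric(glucose@startTime) + (m - 1) * step + step
  out <- et < lo | et > hi
  if (any(out)) {
    warning(sum(out), " event(s) outside the series span by > 1 interval; ",
            "dropped")
  }
  keep <- which(!out)
  idx <- vapply(keep, function(j) {
    d <- abs(gt - et[j])
    # which.min takes the first (earlier) reading on exact ties
    present[which.min(d)]
  }, integer(1))
  eventLog(eventTimes(events)[keep], eventTypes(events)[keep], idx)
}

.emptySeriesLike <- function(x, startTime) {
  new("GlucoseSeries", participantId = x@participantId,
      interval = x@interval, startTime = startTime, values = numeric(0))
}

.subSeries <- function(x, from, to) {
  # grid positions from..to (1-based, inclusive); to < from gives empty
  if (to < from)
    return(.emptySeriesLike(x, x@startTime + (from - 1) * x@interval * 60))
  new("GlucoseSeries", participantId = x@participantId,
      interval = x@interval,
      startTime = x@startTime + (from - 1) * x@interval * 60,
      values = x@values[from:to])
}

.subEvents <- function(e, lo, hi) {
  # events with lo <= time < hi (numeric seconds); grid indices dropped
  t <- as.numeric(eventTimes(e))
  keep <- t >= lo & t < hi
  eventLog(eventTimes(e)[keep], eventTypes(e)[keep])
}

.asParticipant <- function(id, gs, ev) {
  new("ParticipantData", id = id, glucose = gs, events = ev,
      patterns = list(), profiles = list())
}

#' Split a participant's data into train / validation / test
#'
#' The split is by time span: the test set is the final `testSpanDays` of the
#' series, the validation set is the equally long span immediately before it,
#' and training is everything earlier (the usual ~50/25/25 layout when
#' the test span is a quarter of the record). Events travel with their
#' timestamps; an event on a boundary belongs to the later split
#' (half-open ranges).
#'
#' @param glucose a [GlucoseSeries-class].
#' @param events an [EventLog-class] sharing the same time space.
#' @param testSpanDays duration of the test (and validation) range, in days.
#' @return A [DataSplit-class].
#' @export
splitData <- function(glucose, events, testSpanDays) {
  m <- seriesLength(glucose)
  step <- glucose@interval * 60
  nTest <- as.integer(round(testSpanDays * 86400 / step))
  if (nTest < 0L) stop("testSpanDays must be >= 0")
  if (m <= 2L * nTest)
    stop("series spans ", m, " samples; need more than 2 x test span (",
         2L * nTest, ")")
  trainEnd <- m - 2L * nTest            # last train index
  valEnd <- m - nTest                   # last validation index
  t0 <- as.numeric(glucose@startTime)
  bTrainVal <- t0 + trainEnd * step     # first validation timestamp
  bValTest <- t0 + valEnd * step        # first test timestamp
  id <- glucose@participantId
  new("DataSplit",
      train = .asParticipant(id, .subSeries(glucose, 1L, trainEnd),
                             .subEvents(events, -Inf, bTrainVal)),
      validation = .asParticipant(id, .subSeries(glucose, trainEnd + 1L, valEnd),
                                  .subEvents(events, bTrainVal, bValTest)),
      test = .asParticipant(id, .subSeries(glucose, valEnd + 1L, m),
                            .subEvents(events, bValTest, Inf)))
}

setMethod("show", "DataSplit", function(object) {
  for (part in c("train", "validation", "test")) {
    p <- slot(object, part)
    cat(sprintf("%-11s %6d samples  %4d events\n", part,
                seriesLength(p@glucose), nEvents(p@events)))
  }
})

#' @rdname splitData
#' @param x a `DataSplit`.
#' @param part one of `"train"`, `"validation"`, `"test"`.
#' @export
splitPart <- function(x, part = c("train", "validation", "test")) {
  slot(x, match.arg(part))
}
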