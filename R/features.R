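.FEATURE_NAMES <- c("bg", "bg_derivative", "elapsed_hours",
                    "resp_min", "resp_minutes_to_min", "resp_deriv_to_min",
                    "resp_max", "resp_minutes_to_max", "resp_deriv_to_max")

#' Candidate features from a response window
#'
#' The nine per-candidate features the classifiers consume, all computable
#' from the glucose series and the window start alone:
#' \describe{
#'   \item{bg}{glucose at the window start, mg/dl}
#'   \item{bg_derivative}{forward difference over one grid step at the
#'     start, mg/dl/min}
#'   \item{elapsed_hours}{hours since 00:00 (UTC) of the start timestamp's
#'     day, in `[0, 24)`}
#'   \item{resp_min / resp_max}{extremes over the window, mg/dl
#'     (first occurrence on ties)}
#'   \item{resp_minutes_to_min / _max}{minutes from the start to the
#'     extremum}
#'   \item{resp_deriv_to_min / _max}{(extremum - bg) / minutes, mg/dl/min;
#'     0 when the extremum is at the start}
#' }
#'
#' @param glucose a [GlucoseSeries-class].
#' @param startIndex 1-based grid position of the window start.
#' @param params a [selectionParams()] (window length, interval).
#' @return one-row data.frame of the nine features.
#' @export
computeFeatures <- function(glucose, startIndex, params = selectionParams()) {
  n <- params$n
  s <- subsequenceAt(glucose, startIndex, n)
  if (is.null(s))
    stop("window at index ", startIndex,
         " crosses a gap; candidates must be pre-filtered")
  v <- s@values
  dt <- params$interval
  bg <- v[1]
  t0 <- gridTimes(glucose)[startIndex]
  midnight <- as.POSIXct(format(t0, "%Y-%m-%d"), tz = "UTC")
  iMin <- which.min(v)                  # first occurrence on ties
  iMax <- which.max(v)
  minsToMin <- (iMin - 1) * dt
  minsToMax <- (iMax - 1) * dt
  data.frame(
    bg = bg,
    bg_derivative = (v[2] - v[1]) / dt,
    elapsed_hours = as.numeric(difftime(t0, midnight, units = "hours")),
    resp_min = v[iMin],
    resp_minutes_to_min = minsToMin,
    resp_deriv_to_min = if (minsToMin == 0) 0 else (v[iMin] - bg) / minsToMin,
    resp_max = v[iMax],
    resp_minutes_to_max = minsToMax,
    resp_deriv_to_max = if (minsToMax == 0) 0 else (v[iMax] - bg) / minsToMax
  )
}

#' Label candidates against the event log
#'
#' A candidate is labeled `Meal` iff its response start time falls within
#' the closed interval `[t - margin, t + margin]` around some logged meal at
#' `t` (the event's synchronized grid time when available, otherwise its raw
#' timestamp); otherwise `NonMeal`.
#'
#' @param cands candidate data.frame (from [selectCandidates()]).
#' @param glucose the [GlucoseSeries-class] (for synchronized event times).
#' @param events an [EventLog-class].
#' @param params a [selectionParams()] (`marginMinutes`).
#' @return `cands` with a `label` column (`"Meal"` / `"NonMeal"`).
#' @export
labelCandidates <- function(cands, glucose, events,
                            params = selectionParams()) {
  et <- .eventGridTimes(glucose, events)
  margin <- params$marginMinutes * 60
  ct <- as.numeric(cands$start_time)
  lab <- vapply(ct, function(t)
    length(et) > 0 && any(abs(et - t) <= margin), logical(1))
  cands$label <- ifelse(lab, "Meal", "NonMeal")
  cands
}

.eventGridTimes <- function(glucose, events) {
  if (nEvents(events) == 0L) return(numeric(0))
  gi <- eventGridIndex(events)
  t <- as.numeric(eventTimes(events))
  if (any(!is.na(gi))) {
    gt <- as.numeric(gridTimes(glucose))
    t[!is.na(gi)] <- gt[gi[!is.na(gi)]]
  }
  t
}

#' Assemble the classifier training table
#'
#' One row per labeled candidate, plus one positive augmentation row per
#' logged meal that is matched by at least one `Meal` candidate (features
#' computed at the meal's own grid index; skipped when its window is gapped
#' or truncated). Dangling meals — logged meals matched by no candidate —
#' contribute no row: the classifiers are trained on candidates, and those
#' meals support none.
#'
#' @param glucose a [GlucoseSeries-class].
#' @param events a synchronized [EventLog-class].
#' @param cands labeled candidate data.frame (see [labelCandidates()]).
#' @param params a [selectionParams()].
#' @return data.frame: nine feature columns + `label` + `provenance`
#'   (`"candidate"` / `"logged_meal"`).
#' @export
buildTrainingTable <- function(glucose, events, cands,
                               params = selectionParams()) {
  rows <- list()
  for (r in seq_len(nrow(cands))) {
    f <- computeFeatures(glucose, cands$start_index[r], params)
    f$label <- cands$label[r]
    f$provenance <- "candidate"
    rows[[length(rows) + 1L]] <- f
  }
  margin <- params$marginMinutes * 60
  et <- .eventGridTimes(glucose, events)
  ct <- as.numeric(cands$start_time)[cands$label == "Meal"]
  m <- seriesLength(glucose)
  nSkipped <- 0L
  for (j in seq_along(et)) {
    matched <- length(ct) > 0 && any(abs(ct - et[j]) <= margin)
    if (!matched) next                  # dangling meal: no row
    i <- eventGridIndex(events)[j]
    if (is.na(i) || i < 1L || i > m - params$n + 1L ||
        is.null(subsequenceAt(glucose, i, params$n))) {
      nSkipped <- nSkipped + 1L
      next
    }
    f <- computeFeatures(glucose, i, params)
    f$label <- "Meal"
    f$provenance <- "logged_meal"
    rows[[length(rows) + 1L]] <- f
  }
  if (nSkipped > 0L)
    message(nSkipped, " matched meal(s) skipped from augmentation ",
            "(gapped/truncated windows)")
  if (!length(rows)) {
    out <- stats::setNames(
      data.frame(matrix(numeric(0), ncol = length(.FEATURE_NAMES))),
      .FEATURE_NAMES)
    out$label <- character(0)
    out$provenance <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
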