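#' @import methods
NULL

.EVENT_TYPES <- c("breakfast", "lunch", "dinner", "snack", "hypo_correction")

#' GlucoseSeries: a gridded CGM signal
#'
#' A blood-glucose time series sampled on a fixed grid (default 5 minutes).
#' Missing grid positions (sensor gaps) are stored as `NA`, so the object
#' spans `m` grid positions including gaps. Timestamps are derived from
#' `startTime` and `interval`; they are never stored per sample.
#'
#' @slot participantId opaque participant identifier.
#' @slot interval grid spacing in minutes.
#' @slot startTime `POSIXct` (UTC) timestamp of grid position 1.
#' @slot values numeric vector of length `m`; glucose in mg/dl, `NA` at gaps.
#'
#' @seealso [glucoseSeries()], [subsequenceAt()], [gridTimes()]
#' @exportClass GlucoseSeries
setClass("GlucoseSeries",
  representation(
    participantId = "character",
    interval = "numeric",
    startTime = "POSIXct",
    values = "numeric"
  )
)

setValidity("GlucoseSeries", function(object) {
  msg <- character()
  if (length(object@interval) != 1L || !is.finite(object@interval) ||
      object@interval <= 0)
    msg <- c(msg, "interval must be a single positive number of minutes")
  if (length(object@startTime) != 1L)
    msg <- c(msg, "startTime must be a single POSIXct")
  v <- object@values
  bad <- !is.na(v) & (!is.finite(v) | v <= 0)
  if (any(bad))
    msg <- c(msg, "glucose values must be finite and > 0 (NA marks a gap)")
  if (length(msg)) msg else TRUE
})

#' EventLog: timestamped meal events
#'
#' Self-reported meal events (breakfast, lunch, dinner, snack,
#' hypo-correction). After [synchronizeEvents()] each event additionally
#' carries the grid index of the nearest existing glucose reading.
#'
#' @slot times `POSIXct` (UTC), non-decreasing.
#' @slot types character, each one of
#'   `"breakfast"`, `"lunch"`, `"dinner"`, `"snack"`, `"hypo_correction"`.
#' @slot gridIndex integer, `NA` before synchronization.
#'
#' @seealso [eventLog()], [synchronizeEvents()]
#' @exportClass EventLog
setClass("EventLog",
  representation(
    times = "POSIXct",
    types = "character",
    gridIndex = "integer"
  )
)

setValidity("EventLog", function(object) {
  msg <- character()
  k <- length(object@times)
  if (length(object@types) != k || length(object@gridIndex) != k)
    msg <- c(msg, "times, types and gridIndex must have equal length")
  if (k > 1L && any(diff(as.numeric(object@times)) < 0))
    msg <- c(msg, "event timestamps must be non-decreasing")
  if (k > 0L && !all(object@types %in% .EVENT_TYPES))
    msg <- c(msg, paste0("event_type must be one of: ",
                         paste(.EVENT_TYPES, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Subsequence: a contiguous fixed-length window of a GlucoseSeries
#'
#' A meal response is modeled as the contiguous window of `n` samples
#' starting at a grid position `i`, i.e. positions `i .. i+n-1`. Windows
#' containing a gap are never represented; [subsequenceAt()] returns `NULL`
#' for them.
#'
#' @slot startIndex 1-based grid position of the first sample.
#' @slot values the `n` glucose readings (mg/dl), gap-free.
#'
#' @exportClass Subsequence
setClass("Subsequence",
  representation(startIndex = "integer", values = "numeric")
)

setValidity("Subsequence", function(object) {
  msg <- character()
  if (length(object@startIndex) != 1L || object@startIndex < 1L)
    msg <- c(msg, "startIndex must be a single index >= 1")
  if (length(object@values) < 1L || any(!is.finite(object@values)))
    msg <- c(msg, "values must be non-empty, finite (contiguous, no gaps)")
  if (length(msg)) msg else TRUE
})

#' ResponsePattern: an archetypal meal-response shape
#'
#' A z-normalized (zero mean, unit population variance) glucose response
#' shape used as a search query against the signal. Patterns are cluster
#' medoids over observed meal responses, so each pattern is an actually
#' observed response.
#'
#' @slot patternId integer pattern identifier (1-based).
#' @slot values z-normalized shape of length `n`.
#' @slot provenance indices (into the extracted response list) of the
#'   responses in the pattern's cluster; the first element is the medoid.
#'
#' @exportClass ResponsePattern
setClass("ResponsePattern",
  representation(
    patternId = "integer",
    values = "numeric",
    provenance = "integer"
  )
)

setValidity("ResponsePattern", function(object) {
  msg <- character()
  n <- length(object@values)
  if (n < 2L) msg <- c(msg, "pattern must have length >= 2")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "pattern values must be finite")
  if (length(msg)) msg else TRUE
})

#' DistanceProfile: pattern-to-signal distance vector
#'
#' For a pattern of length `n` against a series spanning `m` grid positions,
#' `values[i]` is the z-normalized Euclidean distance between the pattern and
#' the window starting at grid position `i` (length `m - n + 1`). Positions
#' whose window crosses a gap, runs past a contiguous segment, or has zero
#' variance carry the sentinel `Inf`.
#'
#' @slot patternId integer id of the query pattern.
#' @slot n window length in samples.
#' @slot values numeric vector of length `m - n + 1`; finite entries lie in
#'   `[0, 2 * sqrt(n)]`.
#'
#' @seealso [distanceProfile()], [bruteForceProfile()]
#' @exportClass DistanceProfile
setClass("DistanceProfile",
  representation(patternId = "integer", n = "integer", values = "numeric")
)

setValidity("DistanceProfile", function(object) {
  msg <- character()
  v <- object@values
  fin <- v[is.finite(v)]
  n <- object@n
  if (length(n) != 1L || n < 2L) msg <- c(msg, "n must be a single value >= 2")
  if (length(fin) && (any(fin < 0) || any(fin > 2 * sqrt(n) + 1e-8)))
    msg <- c(msg, "finite distances must lie in [0, 2*sqrt(n)]")
  if (any(is.na(v)))
    msg <- c(msg, "profile values must not be NA (use Inf sentinel)")
  if (length(msg)) msg else TRUE
})

#' ParticipantData: the per-participant analysis tuple
#'
#' Bundles everything the pipeline needs for one individual: the glucose
#' series `T`, the event log `E`, the identified response patterns `P` and
#' their distance profiles `D`. `P` and `D` are empty until the training
#' stages fill them; when present, profiles and patterns correspond
#' one-to-one.
#'
#' @slot id participant identifier.
#' @slot glucose [GlucoseSeries-class].
#' @slot events [EventLog-class].
#' @slot patterns list of [ResponsePattern-class].
#' @slot profiles list of [DistanceProfile-class].
#'
#' @exportClass ParticipantData
setClass("ParticipantData",
  representation(
    id = "character",
    glucose = "GlucoseSeries",
    events = "EventLog",
    patterns = "list",
    profiles = "list"
  )
)

setValidity("ParticipantData", function(object) {
  msg <- character()
  if (length(object@profiles) && length(object@profiles) != length(object@patterns))
    msg <- c(msg, "profiles must be empty or match patterns one-to-one")
  if (length(object@patterns) &&
      !all(vapply(object@patterns, is, logical(1), "ResponsePattern")))
    msg <- c(msg, "patterns must contain ResponsePattern objects")
  if (length(object@profiles)) {
    if (!all(vapply(object@profiles, is, logical(1), "DistanceProfile")))
      msg <- c(msg, "profiles must contain DistanceProfile objects")
    else {
      pid <- vapply(object@patterns, function(p) p@patternId, integer(1))
      did <- vapply(object@profiles, function(d) d@patternId, integer(1))
      if (!identical(sort(pid), sort(did)))
        msg <- c(msg, "each profile must reference exactly one pattern")
    }
  }
  if (length(msg)) msg else TRUE
})

#' DataSplit: contiguous train / validation / test partition
#'
#' The three splits are disjoint, ordered time ranges (train before
#' validation before test); validation spans the same duration as test.
#' Each part carries its own glucose sub-series and the events falling in
#' its range.
#'
#' @slot train,validation,test [ParticipantData-class] (patterns/profiles
#'   empty).
#'
#' @seealso [splitData()]
#' @exportClass DataSplit
setClass("DataSplit",
  representation(
    train = "ParticipantData",
    validation = "ParticipantData",
    test = "ParticipantData"
  )
)
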