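#' Candidate-selection parameters
#'
#' The tunable parameters of the detection pipeline, with the defaults used
#' throughout: a 2-hour response window, a 1-hour success margin, three
#' response patterns, a z-normalized distance cutoff of 4, and a 2-hour
#' valley / grouping scale.
#'
#' @param responseMinutes response window length \eqn{\Delta_{response}},
#'   minutes (must be a multiple of `interval`).
#' @param marginMinutes success margin \eqn{\delta_{margin}}, minutes.
#' @param nPatterns number of response patterns |P|.
#' @param dCutoff distance cutoff on the z-normalized profile scale.
#' @param valleyMinutes minimum separation \eqn{\Delta_{valley}} between
#'   selected candidates, minutes; also the temporal-grouping scale.
#' @param groupMinutes dendrogram cut height for global grouping, minutes;
#'   defaults to `valleyMinutes`.
#' @param interval grid spacing, minutes.
#' @return A `SelectionParams` (validated list).
#' @export
selectionParams <- function(responseMinutes = 120, marginMinutes = 60,
                            nPatterns = 3, dCutoff = 4,
                            valleyMinutes = 120,
                            groupMinutes = valleyMinutes, interval = 5) {
  stopifnot(responseMinutes > 0, marginMinutes > 0, nPatterns >= 1,
            dCutoff > 0, valleyMinutes > 0, groupMinutes > 0, interval > 0)
  if (responseMinutes %% interval != 0)
    stop("responseMinutes must be an integer multiple of interval")
  structure(list(responseMinutes = responseMinutes,
                 marginMinutes = marginMinutes,
                 nPatterns = as.integer(nPatterns), dCutoff = dCutoff,
                 valleyMinutes = valleyMinutes, groupMinutes = groupMinutes,
                 interval = interval,
                 n = as.integer(responseMinutes / interval)),
            class = "SelectionParams")
}

#' z-normalize a window
#'
#' Subtracts the mean and divides by the population standard deviation
#' (denominator `n`), the normalization under which z-normalized Euclidean
#' distances are bounded by `2 * sqrt(n)`. A window with (near-)zero
#' variance cannot be shape-normalized; it returns an all-zeros vector
#' flagged with attribute `degenerate = TRUE`.
#'
#' @param x numeric vector (a [Subsequence-class] is accepted), length >= 2.
#' @param eps zero-variance threshold on the sd, mg/dl.
#' @return numeric vector with attribute `degenerate` (logical).
#' @export
znormalize <- function(x, eps = 1e-8) {
  if (is(x, "Subsequence")) x <- x@values
  n <- length(x)
  if (n < 2L) stop("znormalize needs length >= 2")
  mu <- mean(x)
  s <- sqrt(sum((x - mu)^2) / n)
  if (s < eps) {
    z <- numeric(n)
    attr(z, "degenerate") <- TRUE
  } else {
    z <- (x - mu) / s
    attr(z, "degenerate") <- FALSE
  }
  z
}

#' Extract fixed-length meal responses
#'
#' For every synchronized event, takes the window of
#' `responseMinutes / interval` samples starting at the event's grid index.
#' Windows that would run past the series end or straddle a gap are skipped;
#' the number skipped is reported as an attribute and via a message.
#'
#' @param glucose a [GlucoseSeries-class].
#' @param events a synchronized [EventLog-class].
#' @param params a [selectionParams()].
#' @return list of [Subsequence-class] with attribute `nSkipped`.
#' @export
extractMealResponses <- function(glucose, events, params = selectionParams()) {
  if (nEvents(events) > 0L && all(is.na(eventGridIndex(events))))
    stop("events must be synchronized first (see synchronizeEvents)")
  n <- params$n
  m <- seriesLength(glucose)
  out <- list()
  skipped <- 0L
  for (j in seq_len(nEvents(events))) {
    i <- eventGridIndex(events)[j]
    if (is.na(i) || i < 1L || i > m - n + 1L) {
      skipped <- skipped + 1L
      next
    }
    s <- subsequenceAt(glucose, i, n)
    if (is.null(s)) skipped <- skipped + 1L else out[[length(out) + 1L]] <- s
  }
  if (skipped > 0L)
    message(skipped, " of ", nEvents(events),
            " meal responses skipped (gapped or truncated windows)")
  attr(out, "nSkipped") <- skipped
  out
}

#' Identify recurring response patterns
#'
#' z-normalizes the extracted responses (degenerate constant windows are
#' excluded), clusters the shapes by Euclidean distance with agglomerative
#' average-linkage clustering, and represents each cluster by its medoid —
#' the member with minimal summed distance to the rest of its cluster — so
#' every pattern is an actually observed response. Pattern ids follow the
#' time order of their medoids' source responses.
#'
#' @param responses list of [Subsequence-class] (from
#'   [extractMealResponses()]).
#' @param nPatterns number of patterns |P|.
#' @param seed RNG seed, recorded for reproducibility (the clustering itself
#'   is deterministic given the input order).
#' @return list of [ResponsePattern-class] of length `nPatterns`.
#' @export
identifyPatterns <- function(responses, nPatterns = 3, seed = 1L) {
  shapes <- lapply(responses, znormalize)
  keep <- which(!vapply(shapes, attr, logical(1), "degenerate"))
  if (length(keep) < nPatterns)
    stop("only ", length(keep), " non-degenerate responses; need at least ",
         nPatterns, " - use a smaller number of patterns")
  Z <- do.call(rbind, shapes[keep])
  if (length(keep) == nPatterns) {
    cl <- seq_len(nPatterns)
  } else {
    hc <- stats::hclust(stats::dist(Z), method = "average")
    cl <- stats::cutree(hc, k = nPatterns)
  }
  if (length(unique(apply(Z, 1, paste, collapse = ","))) == 1L)
    message("all responses identical; returned patterns coincide")
  medoids <- integer(nPatterns)
  for (g in seq_len(nPatterns)) {
    members <- which(cl == g)
    if (length(members) == 1L) {
      medoids[g] <- members
    } else {
      Dg <- as.matrix(stats::dist(Z[members, , drop = FALSE]))
      medoids[g] <- members[which.min(rowSums(Dg))]
    }
  }
  ord <- order(keep[medoids])  # stable ids by source-response time order
  out <- vector("list", nPatterns)
  for (p in seq_len(nPatterns)) {
    g <- ord[p]
    members <- keep[cl == g]
    med <- keep[medoids[g]]
    out[[p]] <- new("ResponsePattern", patternId = p,
                    values = as.numeric(Z[medoids[g], ]),
                    provenance = as.integer(c(med, setdiff(members, med))))
  }
  out
}
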