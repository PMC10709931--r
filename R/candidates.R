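#' Valley-based candidate positions from one distance profile
#'
#' Implements the per-pattern match search: candidate positions are strict
#' local minima of the profile with distance below `dCutoff`, selected
#' greedily in ascending distance order while suppressing any remaining
#' minimum within `valleyWindow` samples of an already selected one, so
#' selected candidates within one pattern are always at least
#' `valleyWindow` samples apart. Plateau minima (runs of equal values lower
#' than both neighbors) contribute their leftmost index; profile ends and
#' `Inf` sentinels act as high neighbors.
#'
#' @param profile a [DistanceProfile-class].
#' @param dCutoff distance cutoff (z-normalized scale).
#' @param valleyWindow minimum separation in samples
#'   (`valleyMinutes / interval`).
#' @return data.frame with columns `start_index`, `pattern_id`, `distance`,
#'   sorted by `start_index`.
#' @export
getValleys <- function(profile, dCutoff, valleyWindow) {
  d <- profile@values
  L <- length(d)
  if (L == 0L) return(.emptyCandidates())
  left <- c(Inf, d[-L])
  right <- c(d[-1], Inf)
  # leftmost index of each minimal plateau: strictly below the previous
  # distinct value and not above the next value, with the plateau's right
  # end strictly below its right neighbor
  r <- rle(d)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  vals <- r$values
  nRuns <- length(vals)
  lo <- c(Inf, vals[-nRuns])
  hi <- c(vals[-1], Inf)
  isMin <- is.finite(vals) & vals < lo & vals < hi & vals < dCutoff
  pos <- starts[isMin]
  dv <- vals[isMin]
  if (!length(pos)) return(.emptyCandidates())
  ord <- order(dv, pos)
  keep <- integer(0)
  for (j in ord) {
    if (!length(keep) || all(abs(pos[keep] - pos[j]) >= valleyWindow))
      keep <- c(keep, j)
  }
  keep <- keep[order(pos[keep])]
  data.frame(start_index = pos[keep],
             pattern_id = rep(profile@patternId, length(keep)),
             distance = dv[keep])
}

.emptyCandidates <- function() {
  data.frame(start_index = integer(0), pattern_id = integer(0),
             distance = numeric(0))
}

#' Group near-in-time candidates across patterns
#'
#' The global grouping step: candidate start times are clustered with 1-D
#' agglomerative average-linkage clustering and the dendrogram is cut at
#' `groupMinutes`; each cluster contributes exactly its minimum-distance
#' member (ties broken toward the earlier time, then the lower pattern id).
#'
#' @param cands data.frame with `start_index`, `start_time`, `pattern_id`,
#'   `distance` (pooled across patterns).
#' @param groupMinutes dendrogram cut height, minutes.
#' @return data.frame of cluster representatives, sorted by time.
#' @export
groupCandidates <- function(cands, groupMinutes) {
  k <- nrow(cands)
  if (k <= 1L) return(cands)
  mins <- as.numeric(cands$start_time) / 60
  hc <- stats::hclust(stats::dist(mins), method = "average")
  # merge strictly-closer-than-the-scale clusters: candidates exactly
  # groupMinutes apart (the valley-suppression boundary) stay separate
  cl <- stats::cutree(hc, h = groupMinutes * (1 - 1e-9))
  pick <- vapply(split(seq_len(k), cl), function(ix) {
    o <- order(cands$distance[ix], mins[ix], cands$pattern_id[ix])
    ix[o[1]]
  }, integer(1))
  out <- cands[sort(pick), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select meal-response candidates from the distance profiles
#'
#' Full selection: per-pattern valley search below `dCutoff` with
#' `valleyMinutes` suppression, pooled over all patterns, then global
#' temporal grouping at `groupMinutes`. Windows crossing gaps were assigned
#' `Inf` upstream and can never be selected; this is asserted here.
#'
#' @param glucose the [GlucoseSeries-class] the profiles were computed on.
#' @param profiles list of [DistanceProfile-class] (one per pattern).
#' @param params a [selectionParams()].
#' @return data.frame with `start_index`, `start_time`, `pattern_id`,
#'   `distance`, sorted by time.
#' @export
selectCandidates <- function(glucose, profiles, params = selectionParams()) {
  w <- params$valleyMinutes / params$interval
  per <- lapply(profiles, getValleys, dCutoff = params$dCutoff,
                valleyWindow = w)
  cands <- do.call(rbind, per)
  if (is.null(cands) || nrow(cands) == 0L) {
    warning("no profile value below dCutoff anywhere; no candidates selected")
    out <- .emptyCandidates()
    out$start_time <- as.POSIXct(character(), tz = "UTC")
    return(out[, c("start_index", "start_time", "pattern_id", "distance")])
  }
  gaps <- is.na(glucose@values)
  n <- params$n
  contiguous <- vapply(cands$start_index, function(i)
    !any(gaps[i:(i + n - 1L)]), logical(1))
  stopifnot(all(contiguous))  # Inf sentinels guarantee this upstream
  cands$start_time <- gridTimes(glucose)[cands$start_index]
  cands <- cands[order(cands$start_time, cands$pattern_id), , drop = FALSE]
  rownames(cands) <- NULL
  out <- groupCandidates(cands, params$groupMinutes)
  out[, c("start_index", "start_time", "pattern_id", "distance")]
}

#' Top-n candidate selection (baseline)
#'
#' The fixed-count alternative the valley procedure replaces: per pattern,
#' the `nTop` positions with the smallest finite profile distances, with no
#' suppression or grouping. Kept as a comparison baseline.
#'
#' @param profiles list of [DistanceProfile-class].
#' @param nTop matches kept per pattern (>= 1); if it exceeds the number of
#'   finite positions, all are returned.
#' @return data.frame with `start_index`, `pattern_id`, `distance`.
#' @export
topNSelect <- function(profiles, nTop) {
  if (nTop < 1L) stop("nTop must be >= 1")
  out <- lapply(profiles, function(p) {
    fin <- which(is.finite(p@values))
    if (!length(fin)) return(.emptyCandidates())
    o <- fin[order(p@values[fin], fin)]
    o <- o[seq_len(min(nTop, length(o)))]
    o <- sort(o)
    data.frame(start_index = o,
               pattern_id = rep(p@patternId, length(o)),
               distance = p@values[o])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
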