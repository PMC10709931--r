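#' Match predicted meals to logged meals within a margin
#'
#' One-to-one greedy matching: all prediction/meal pairs with
#' `|t_pred - t_meal| <= margin` are considered in ascending time-difference
#' order (ties toward the earlier prediction, then the earlier meal); each
#' prediction and each meal is used at most once. Matched pairs are true
#' positives, unmatched predictions false positives, unmatched meals false
#' negatives — so `tp + fp = predictions` and `tp + fn = meals` always hold.
#'
#' @param predTimes `POSIXct` predicted meal times, sorted.
#' @param mealTimes `POSIXct` logged meal times, sorted.
#' @param marginMinutes matching margin \eqn{\delta_{margin}}, minutes
#'   (closed interval).
#' @return list: `matching` (data.frame `pred`, `meal` index pairs) and
#'   `counts` (named list `meals`, `predictions`, `tp`, `fp`, `fn`).
#' @export
matchEvents <- function(predTimes, mealTimes, marginMinutes = 60) {
  p <- as.numeric(predTimes)
  e <- as.numeric(mealTimes)
  margin <- marginMinutes * 60
  pairs <- NULL
  if (length(p) && length(e)) {
    grid <- expand.grid(pred = seq_along(p), meal = seq_along(e))
    grid$dt <- abs(p[grid$pred] - e[grid$meal])
    grid <- grid[grid$dt <= margin, , drop = FALSE]
    grid <- grid[order(grid$dt, p[grid$pred], e[grid$meal]), , drop = FALSE]
    usedP <- logical(length(p))
    usedE <- logical(length(e))
    keep <- logical(nrow(grid))
    for (r in seq_len(nrow(grid))) {
      i <- grid$pred[r]; j <- grid$meal[r]
      if (!usedP[i] && !usedE[j]) {
        usedP[i] <- TRUE; usedE[j] <- TRUE; keep[r] <- TRUE
      }
    }
    pairs <- grid[keep, c("pred", "meal"), drop = FALSE]
    rownames(pairs) <- NULL
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  list(matching = pairs,
       counts = list(meals = length(e), predictions = length(p),
                     tp = tp, fp = length(p) - tp, fn = length(e) - tp))
}

.metricsFromCounts <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp == 0)
    return(list(ppv = 0, tpr = 0, f1 = 0, f2 = 0))
  list(ppv = tp / (tp + fp), tpr = tp / (tp + fn),
       f1 = fBeta(tp, fp, fn, 1), f2 = fBeta(tp, fp, fn, 2))
}

.reportRow <- function(counts, scope, day = NA) {
  m <- .metricsFromCounts(counts)
  data.frame(day = as.character(day), scope = scope,
             meals = counts$meals, predictions = counts$predictions,
             fp = counts$fp, fn = counts$fn, tp = counts$tp,
             ppv = m$ppv, tpr = m$tpr, f1 = m$f1, f2 = m$f2)
}

#' Per-day detection reports
#'
#' Partitions predictions and logged meals by calendar day (local midnight,
#' UTC) and evaluates each day independently with [matchEvents()]. Days with
#' neither meals nor predictions are omitted.
#'
#' @inheritParams matchEvents
#' @return data.frame, one row per day: `day`, `scope = "day"`, counts and
#'   PPV/TPR/F1/F2.
#' @export
dailyReports <- function(predTimes, mealTimes, marginMinutes = 60) {
  pd <- format(predTimes, "%Y-%m-%d", tz = "UTC")
  md <- format(mealTimes, "%Y-%m-%d", tz = "UTC")
  days <- sort(unique(c(pd, md)))
  rows <- lapply(days, function(d) {
    mc <- matchEvents(predTimes[pd == d], mealTimes[md == d], marginMinutes)
    .reportRow(mc$counts, "day", d)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- .reportRow(list(meals = 0L, predictions = 0L,
                                           tp = 0L, fp = 0L, fn = 0L),
                                      "day")[0, ]
  rownames(out) <- NULL
  out
}

#' Aggregate per-day reports
#'
#' `pooled`: counts are summed over days and the metrics recomputed from the
#' sums (whole-split totals). `macro`: counts *and* metrics are averaged
#' arithmetically over days (the per-day "Average" convention) — the two
#' differ whenever daily precision varies with daily volume.
#'
#' @param reports data.frame from [dailyReports()] (or any rows with the
#'   same columns).
#' @param mode `"pooled"` or `"macro"`.
#' @return one-row data.frame with `scope` `"split-pooled"` or
#'   `"split-macro"`.
#' @export
aggregateReports <- function(reports, mode = c("pooled", "macro")) {
  mode <- match.arg(mode)
  if (nrow(reports) == 0L) stop("no reports to aggregate")
  if (mode == "pooled") {
    counts <- list(meals = sum(reports$meals),
                   predictions = sum(reports$predictions),
                   tp = sum(reports$tp), fp = sum(reports$fp),
                   fn = sum(reports$fn))
    return(.reportRow(counts, "split-pooled"))
  }
  data.frame(day = NA_character_, scope = "split-macro",
             meals = mean(reports$meals),
             predictions = mean(reports$predictions),
             fp = mean(reports$fp), fn = mean(reports$fn),
             tp = mean(reports$tp),
             ppv = mean(reports$ppv), tpr = mean(reports$tpr),
             f1 = mean(reports$f1), f2 = mean(reports$f2))
}

#' Write a metrics report as CSV
#'
#' Column layout `meals,predictions,fp,fn,tp,ppv,tpr,f1,f2` (plus `day` and
#' `scope`).
#'
#' @param report data.frame of report rows.
#' @param path output path.
#' @export
writeReportCSV <- function(report, path) {
  utils::write.csv(report[, c("day", "scope", "meals", "predictions",
                              "fp", "fn", "tp", "ppv", "tpr", "f1", "f2")],
                   path, row.names = FALSE)
  invisible(path)
}
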