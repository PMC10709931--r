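#' Run the training pipeline on one participant
#'
#' Executes the full training sequence on the train split — synchronize
#' events, extract meal responses, identify patterns, compute distance
#' profiles, select and label candidates, assemble the training table with
#' matched-meal augmentation, fit the six classifiers — then selects the
#' participant's model by F2 on the validation split. Identical seeds give
#' identical artifacts.
#'
#' @param split a [DataSplit-class] (train and validation must contain
#'   events).
#' @param params a [selectionParams()].
#' @param seed integer seed for the stochastic learners.
#' @return list: `patterns`, `profiles` (train-split), `candidates`,
#'   `trainingTable`, `models`, `selection` (see [selectModel()]), `params`,
#'   `seed`.
#' @export
runTrain <- function(split, params = selectionParams(), seed = 1L) {
  train <- splitPart(split, "train")
  if (nEvents(train@events) == 0L)
    stop("pattern stage: no meal events in the training split")
  ev <- synchronizeEvents(train@glucose, train@events)
  responses <- extractMealResponses(train@glucose, ev, params)
  patterns <- identifyPatterns(responses, params$nPatterns, seed)
  profiles <- lapply(patterns, function(p) distanceProfile(train@glucose, p))
  cands <- selectCandidates(train@glucose, profiles, params)
  cands <- labelCandidates(cands, train@glucose, ev, params)
  tab <- buildTrainingTable(train@glucose, ev, cands, params)
  models <- trainAll(tab, seed)
  selection <- selectModel(models, splitPart(split, "validation"),
                           patterns, params)
  list(patterns = patterns, profiles = profiles, candidates = cands,
       trainingTable = tab, models = models, selection = selection,
       params = params, seed = as.integer(seed))
}

#' Detect meals on the test split
#'
#' Applies the trained artifacts to unseen data: candidates are selected on
#' the test span with the training-time patterns, featurized, and classified
#' by the selected model; predictions are evaluated against the test-split
#' event log per day and pooled.
#'
#' @param trained result of [runTrain()].
#' @param test a [ParticipantData-class] (the test split).
#' @param model optional model override; defaults to the selected one.
#' @return list: `predictions` (`POSIXct`), `candidates`, `daily`
#'   (per-day report), `pooled`, `macro` (one-row reports).
#' @export
runDetect <- function(trained, test, model = trained$selection$model) {
  if (is.null(trained$patterns) || is.null(model))
    stop("trained artifacts (patterns, selected model) are required")
  params <- trained$params
  det <- detectOnSplit(test, trained$patterns, params,
                       stats::setNames(list(model), model$name))
  pred <- det$predTimes[[model$name]]
  mealT <- .eventTimesForEval(test)
  daily <- dailyReports(pred, mealT, params$marginMinutes)
  list(predictions = pred, candidates = det$candidates, daily = daily,
       pooled = aggregateReports(daily, "pooled"),
       macro = aggregateReports(daily, "macro"))
}

# ---- artifact serialization ------------------------------------------------

#' Persist and reload pipeline artifacts as plain text
#'
#' Patterns go to JSON (`pattern_id`, `values`, `provenance`); profiles to
#' JSON arrays keyed by pattern id with the `Inf` sentinel serialized as
#' `null`; candidate sets to CSV
#' (`start_time,pattern_id,distance,label,prediction`, blanks when absent).
#'
#' @param patterns list of [ResponsePattern-class].
#' @param path output path.
#' @name artifact-io
#' @export
writePatternsJSON <- function(patterns, path) {
  obj <- lapply(patterns, function(p)
    list(pattern_id = p@patternId, values = p@values,
         provenance = p@provenance))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname artifact-io
#' @export
readPatternsJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(obj)), function(i)
    new("ResponsePattern", patternId = as.integer(obj$pattern_id[i]),
        values = as.numeric(obj$values[[i]]),
        provenance = as.integer(obj$provenance[[i]])))
}

#' @rdname artifact-io
#' @param profiles list of [DistanceProfile-class].
#' @export
writeProfilesJSON <- function(profiles, path) {
  obj <- lapply(profiles, function(d) {
    v <- d@values
    v[!is.finite(v)] <- NA_real_
    list(pattern_id = d@patternId, n = d@n, values = v)
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname artifact-io
#' @param cands candidate data.frame.
#' @export
writeCandidatesCSV <- function(cands, path) {
  df <- data.frame(start_time = .fmtTime(cands$start_time),
                   pattern_id = cands$pattern_id,
                   distance = cands$distance,
                   label = if ("label" %in% names(cands)) cands$label else "",
                   prediction = if ("prediction" %in% names(cands))
                     cands$prediction else "")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
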