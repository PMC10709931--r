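.CLASSIFIERS <- c("AdaBoost", "DecisionTree", "GradientBoosting",
                  "GaussianNB", "MLP", "RandomForest")

# ---- discrete AdaBoost (SAMME) over depth-1 rpart stumps -------------------
# Binary boosting with reweighted decision stumps: 50 rounds, learning rate 1.
.fitAdaBoost <- function(X, y, nRounds = 50) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  yy <- ifelse(y == "Meal", 1, -1)
  stumps <- list()
  alphas <- numeric(0)
  df <- cbind(X, .y = factor(y, levels = c("NonMeal", "Meal")))
  for (r in seq_len(nRounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1,
                                                       cp = -1, minsplit = 2,
                                                       xval = 0))
    pred <- ifelse(predict(fit, X, type = "class") == "Meal", 1, -1)
    err <- sum(w * (pred != yy))
    if (err <= 0) {                      # perfect stump: take it and stop
      stumps[[length(stumps) + 1L]] <- fit
      alphas <- c(alphas, 10)
      break
    }
    if (err >= 0.5) break                # no better than chance: stop
    a <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, a)
    w <- w * exp(-a * yy * pred)
    w <- w / sum(w)
  }
  if (!length(stumps)) {                 # degenerate: fall back to majority
    maj <- names(which.max(table(y)))
    return(list(stumps = list(), alphas = numeric(0), majority = maj))
  }
  list(stumps = stumps, alphas = alphas, majority = NULL)
}

.predictAdaBoost <- function(fit, X) {
  if (!length(fit$stumps))
    return(rep(fit$majority, nrow(X)))
  score <- rep(0, nrow(X))
  for (r in seq_along(fit$stumps)) {
    p <- ifelse(predict(fit$stumps[[r]], X, type = "class") == "Meal", 1, -1)
    score <- score + fit$alphas[r] * p
  }
  ifelse(score > 0, "Meal", "NonMeal")
}

#' Train the six binary classifier types
#'
#' Fits one model of each type on the training table with library-default
#' hyperparameters (stochastic learners seeded): a boosted-stump ensemble
#' (AdaBoost), a CART decision tree, gradient-boosted trees, Gaussian naive
#' Bayes, a single-hidden-layer perceptron (features standardized
#' internally), and a random forest. The hyperparameters actually used are
#' attached to each model (`$params`).
#'
#' @param table training table from [buildTrainingTable()] (needs at least
#'   one `Meal` and one `NonMeal` row).
#' @param seed integer seed applied before each stochastic fit.
#' @return named list of `TrainedModel` lists
#'   (`name`, `fit`, `featureNames`, `seed`, `params`, plus scaling for the
#'   MLP); predict with [predictMeal()].
#' @export
trainAll <- function(table, seed = 1L) {
  if (nrow(table) == 0L) stop("training table is empty")
  for (cls in c("Meal", "NonMeal"))
    if (!any(table$label == cls))
      stop("training table has no '", cls, "' rows; cannot train")
  X <- table[, .FEATURE_NAMES, drop = FALSE]
  y <- factor(table$label, levels = c("NonMeal", "Meal"))
  yNum <- as.integer(y == "Meal")
  models <- list()

  set.seed(seed)
  models$AdaBoost <- list(
    name = "AdaBoost", fit = .fitAdaBoost(X, as.character(y)),
    params = list(nRounds = 50, baseLearner = "stump"))

  set.seed(seed)
  models$DecisionTree <- list(
    name = "DecisionTree",
    fit = rpart::rpart(y ~ ., data = cbind(X, y = y), method = "class"),
    params = list(defaults = "rpart"))

  set.seed(seed)
  models$GradientBoosting <- list(
    name = "GradientBoosting",
    fit = xgboost::xgb.train(
      params = list(objective = "binary:logistic", nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(X), label = yNum, nthread = 1),
      nrounds = 100, verbose = 0),
    params = list(nrounds = 100, objective = "binary:logistic"))

  set.seed(seed)
  models$GaussianNB <- list(
    name = "GaussianNB",
    fit = e1071::naiveBayes(X, y),
    params = list(defaults = "naiveBayes"))

  set.seed(seed)
  center <- vapply(X, mean, numeric(1))
  scale <- vapply(X, stats::sd, numeric(1))
  scale[scale < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  models$MLP <- list(
    name = "MLP",
    fit = nnet::nnet(Xs, yNum, size = 8, decay = 1e-4, maxit = 300,
                     trace = FALSE),
    center = center, scale = scale,
    params = list(size = 8, decay = 1e-4, maxit = 300))

  set.seed(seed)
  models$RandomForest <- list(
    name = "RandomForest",
    fit = randomForest::randomForest(X, y),
    params = list(ntree = 500))

  for (nm in names(models)) {
    models[[nm]]$featureNames <- .FEATURE_NAMES
    models[[nm]]$seed <- as.integer(seed)
  }
  models
}

#' Predict Meal / NonMeal for candidate features
#'
#' @param model one element of [trainAll()]'s result.
#' @param features data.frame containing the nine feature columns.
#' @return character vector of `"Meal"` / `"NonMeal"`.
#' @export
predictMeal <- function(model, features) {
  X <- features[, model$featureNames, drop = FALSE]
  if (nrow(X) == 0L) return(character(0))
  out <- switch(model$name,
    AdaBoost = .predictAdaBoost(model$fit, X),
    DecisionTree = as.character(predict(model$fit, X, type = "class")),
    GradientBoosting = ifelse(
      predict(model$fit,
              xgboost::xgb.DMatrix(as.matrix(X), nthread = 1)) > 0.5,
      "Meal", "NonMeal"),
    GaussianNB = as.character(predict(model$fit, X)),
    MLP = {
      Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
      ifelse(predict(model$fit, Xs) > 0.5, "Meal", "NonMeal")
    },
    RandomForest = as.character(predict(model$fit, X)),
    stop("unknown classifier '", model$name, "'")
  )
  unname(out)
}

#' F-beta score from confusion counts
#'
#' `PPV = tp/(tp+fp)`, `TPR = tp/(tp+fn)`,
#' `F_beta = (1+beta^2) * PPV * TPR / (beta^2 * PPV + TPR)`.
#' Returns 0 when `tp = 0` (the undefined-precision/recall convention);
#' all-zero counts are an error.
#'
#' @param tp,fp,fn confusion counts.
#' @param beta recall weight (`beta = 2` weights recall over precision).
#' @return score in `[0, 1]`.
#' @examples
#' fBeta(32, 17, 11, beta = 2)   # 0.72
#' @export
fBeta <- function(tp, fp, fn, beta = 1) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, beta > 0)
  if (tp + fp + fn == 0) stop("all-zero confusion counts")
  if (tp == 0) return(0)
  ppv <- tp / (tp + fp)
  tpr <- tp / (tp + fn)
  (1 + beta^2) * ppv * tpr / (beta^2 * ppv + tpr)
}

#' Select the participant's model by validation F2
#'
#' Runs every trained model through the full event-level pipeline on the
#' validation split — candidate selection with the training-time patterns,
#' featurization, prediction, margin-based matching against the validation
#' events — and keeps the model with the highest F2 score. Ties go to the
#' higher F1, then to a fixed name order.
#'
#' @param models list from [trainAll()].
#' @param validation a [ParticipantData-class] (the validation split).
#' @param patterns training-time list of [ResponsePattern-class].
#' @param params a [selectionParams()].
#' @return list: `report` (one row per classifier: counts + PPV/TPR/F1/F2,
#'   sorted by F2), `selected` (classifier name), `model` (the winner).
#' @export
selectModel <- function(models, validation, patterns,
                        params = selectionParams()) {
  ev <- validation@events
  if (nEvents(ev) == 0L)
    stop("validation split contains no events; cannot select a model")
  det <- detectOnSplit(validation, patterns, params, models)
  rows <- lapply(.CLASSIFIERS, function(nm) {
    pt <- det$predTimes[[nm]]
    mc <- matchEvents(pt, .eventTimesForEval(validation), params$marginMinutes)
    c(list(classifier = nm), as.list(mc$counts),
      .metricsFromCounts(mc$counts))
  })
  report <- do.call(rbind, lapply(rows, as.data.frame))
  ord <- order(-report$f2, -report$f1, match(report$classifier, .CLASSIFIERS))
  report <- report[ord, , drop = FALSE]
  rownames(report) <- NULL
  sel <- report$classifier[1]
  list(report = report, selected = sel, model = models[[sel]])
}

# predicted meal times per classifier on one split
detectOnSplit <- function(part, patterns, params, models) {
  segs <- .contiguousSegments(part@glucose@values)
  maxSeg <- if (length(segs))
    max(vapply(segs, function(s) s[2] - s[1] + 1L, integer(1))) else 0L
  if (maxSeg < params$n) {
    # signal too gapped to host a single response window: nothing to select
    cands <- .emptyCandidates()
    cands$start_time <- as.POSIXct(character(), tz = "UTC")
  } else {
    profiles <- lapply(patterns, function(p) distanceProfile(part@glucose, p))
    cands <- suppressWarnings(selectCandidates(part@glucose, profiles, params))
  }
  if (nrow(cands) == 0L) {
    empty <- as.POSIXct(character(), tz = "UTC")
    return(list(candidates = cands,
                predTimes = stats::setNames(
                  rep(list(empty), length(models)), names(models))))
  }
  feats <- do.call(rbind, lapply(cands$start_index, computeFeatures,
                                 glucose = part@glucose, params = params))
  predTimes <- lapply(models, function(mdl) {
    p <- predictMeal(mdl, feats)
    sort(cands$start_time[p == "Meal"])
  })
  list(candidates = cands, features = feats, predTimes = predTimes)
}

.eventTimesForEval <- function(part) {
  if (all(is.na(part@glucose@values)))   # nothing to synchronize against
    return(eventTimes(part@events))
  ev <- synchronizeEvents(part@glucose, part@events)
  as.POSIXct(.eventGridTimes(part@glucose, ev),
             origin = "1970-01-01", tz = "UTC")
}
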