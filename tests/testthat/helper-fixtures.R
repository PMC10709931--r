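# builders ------------------------------------------------------------------

t0utc <- function(s = "2023-04-01 00:00:00") as.POSIXct(s, tz = "UTC")

# series straight from a value vector (NA = gap), bypassing CSV snapping
makeSeries <- function(values, start = t0utc(), interval = 5, id = "t") {
  new("GlucoseSeries", participantId = id, interval = interval,
      startTime = start, values = as.numeric(values))
}

makeProfile <- function(values, n = 24L, pid = 1L) {
  new("DistanceProfile", patternId = as.integer(pid), n = as.integer(n),
      values = as.numeric(values))
}

# reference per-participant validation results (counts + printed metrics)
validationResultsFixture <- function() {
  read.csv(text = "id,meals,predictions,fp,fn,tp,ppv,tpr,f1,f2
540,23,9,4,18,5,0.56,0.22,0.31,0.25
544,31,43,15,3,28,0.65,0.90,0.76,0.84
552,3,14,13,2,1,0.07,0.33,0.12,0.19
559,25,32,18,11,14,0.44,0.56,0.49,0.53
563,25,34,19,10,15,0.44,0.60,0.51,0.56
567,1,6,5,0,1,0.17,1.00,0.29,0.50
570,29,40,19,8,21,0.52,0.72,0.61,0.67
575,46,53,17,10,36,0.68,0.78,0.73,0.76
584,15,20,11,6,9,0.45,0.60,0.51,0.56
588,43,49,17,11,32,0.65,0.74,0.70,0.72
591,40,65,35,10,30,0.46,0.75,0.57,0.67
596,44,54,25,15,29,0.54,0.66,0.59,0.63")
}

# reference per-participant test results
testResultsFixture <- function() {
  read.csv(text = "id,meals,predictions,fp,fn,tp,ppv,tpr,f1,f2
540,20,9,8,19,1,0.11,0.05,0.07,0.06
544,32,38,9,3,29,0.76,0.91,0.83,0.87
552,14,18,12,8,6,0.33,0.43,0.38,0.41
559,23,31,20,12,11,0.35,0.48,0.41,0.45
563,23,28,18,13,10,0.36,0.43,0.39,0.42
570,31,37,13,7,24,0.65,0.77,0.71,0.75
575,37,42,18,13,24,0.57,0.65,0.61,0.63
584,20,34,23,9,11,0.32,0.55,0.41,0.48
588,34,50,25,9,25,0.50,0.74,0.60,0.67
591,37,64,38,11,26,0.41,0.70,0.51,0.61
596,45,59,27,13,32,0.54,0.71,0.62,0.67")
}

# reference per-classifier model-selection results for one participant
# (43 validation meals)
modelComparisonFixture <- function() {
  read.csv(text = "classifier,predictions,fp,fn,tp,ppv,tpr,f1,f2
AdaBoost,49,17,11,32,0.65,0.74,0.70,0.72
RandomForest,41,12,14,29,0.71,0.67,0.69,0.68
GradientBoosting,47,17,13,30,0.64,0.70,0.67,0.68
DecisionTree,38,13,18,25,0.66,0.58,0.62,0.60
MLP,38,13,18,25,0.66,0.58,0.62,0.60
GaussianNB,36,15,22,21,0.58,0.49,0.53,0.50")
}

# reference per-day validation results for the same participant, with the
# printed macro Average row last
perDayValidationFixture <- function() {
  list(days = read.csv(text = "day,meals,predictions,fp,fn,tp,ppv,tpr,f1,f2
2021-10-05,4,6,2,0,4,0.67,1.00,0.80,0.91
2021-10-06,4,6,2,0,4,0.67,1.00,0.80,0.91
2021-10-07,4,5,2,1,3,0.60,0.75,0.67,0.71
2021-10-08,5,4,1,2,3,0.75,0.60,0.67,0.62
2021-10-09,3,5,3,1,2,0.40,0.67,0.50,0.59
2021-10-10,3,2,1,2,1,0.50,0.33,0.40,0.36
2021-10-11,5,6,2,1,4,0.67,0.80,0.73,0.77
2021-10-12,6,4,2,4,2,0.50,0.33,0.40,0.36
2021-10-13,4,6,2,0,4,0.67,1.00,0.80,0.91
2021-10-14,5,5,0,0,5,1.00,1.00,1.00,1.00"),
       average = c(meals = 4.3, predictions = 4.9, fp = 1.7, fn = 1.1,
                   tp = 3.2, ppv = 0.64, tpr = 0.75, f1 = 0.68, f2 = 0.71))
}

# reference per-day test results for the same participant
perDayTestFixture <- function() {
  list(days = read.csv(text = "day,meals,predictions,fp,fn,tp,ppv,tpr,f1,f2
2021-10-15,5,4,3,4,1,0.25,0.20,0.22,0.21
2021-10-16,2,3,2,1,1,0.33,0.50,0.40,0.45
2021-10-17,4,8,6,2,2,0.25,0.50,0.33,0.42
2021-10-18,3,2,1,2,1,0.50,0.33,0.40,0.36
2021-10-19,4,7,3,0,4,0.57,1.00,0.73,0.87
2021-10-20,4,6,2,0,4,0.67,1.00,0.80,0.91
2021-10-21,4,4,0,0,4,1.00,1.00,1.00,1.00
2021-10-22,2,5,3,0,2,0.40,1.00,0.57,0.77
2021-10-23,2,3,1,0,2,0.67,1.00,0.80,0.91
2021-10-24,4,8,4,0,4,0.50,1.00,0.67,0.83"),
       average = c(meals = 3.4, predictions = 5.0, fp = 2.5, fn = 0.9,
                   tp = 2.5, ppv = 0.51, tpr = 0.75, f1 = 0.59, f2 = 0.67))
}

metricsFor <- function(tp, fp, fn) {
  if (tp == 0) return(c(ppv = 0, tpr = 0, f1 = 0, f2 = 0))
  c(ppv = tp / (tp + fp), tpr = tp / (tp + fn),
    f1 = fBeta(tp, fp, fn, 1), f2 = fBeta(tp, fp, fn, 2))
}
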