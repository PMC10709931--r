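test_that("greedy one-to-one matching yields the expected counts", {
  day <- function(s) t0utc(paste("2023-04-01", s))
  mc <- matchEvents(c(day("08:30:00"), day("08:45:00"), day("13:30:00")),
                    c(day("08:00:00"), day("12:00:00")), 60)
  expect_equal(mc$counts, list(meals = 2L, predictions = 3L,
                               tp = 1L, fp = 2L, fn = 1L))
  # the closer prediction (08:30) is the one matched
  expect_equal(mc$matching$pred, 1L)
  expect_equal(mc$matching$meal, 1L)
  # perfect prediction
  m <- c(day("08:00:00"), day("12:00:00"), day("18:00:00"))
  mc2 <- matchEvents(m, m, 60)
  expect_equal(mc2$counts$tp, 3L)
  expect_equal(mc2$counts$fp, 0L)
  expect_equal(mc2$counts$fn, 0L)
  # four predictions each within margin of a distinct meal: 4/4 matched
  meals4 <- day(c("07:30:00", "12:00:00", "16:00:00", "19:30:00"))
  preds4 <- meals4 + c(900, -1200, 1800, 600)
  mc4 <- matchEvents(preds4, meals4, 60)
  expect_equal(mc4$counts[c("tp", "fp", "fn")], list(tp = 4L, fp = 0L, fn = 0L))
  # one-to-one: two predictions cannot consume the same meal
  mc5 <- matchEvents(day(c("08:10:00", "08:20:00")), day("08:00:00"), 60)
  expect_equal(mc5$counts[c("tp", "fp", "fn")], list(tp = 1L, fp = 1L, fn = 0L))
})

test_that("matching role reversal swaps fp and fn", {
  set.seed(83)
  a <- t0utc() + sort(runif(12, 0, 86400))
  b <- t0utc() + sort(runif(9, 0, 86400))
  ab <- matchEvents(a, b, 60)$counts
  ba <- matchEvents(b, a, 60)$counts
  expect_equal(ab$tp, ba$tp)
  expect_equal(ab$fp, ba$fn)
  expect_equal(ab$fn, ba$fp)
})

test_that("count identities hold across the reference per-participant rows", {
  for (fx in list(validationResultsFixture(), testResultsFixture())) {
    expect_equal(fx$tp + fx$fp, fx$predictions)
    expect_equal(fx$tp + fx$fn, fx$meals)
  }
  cmp <- modelComparisonFixture()
  expect_equal(cmp$tp + cmp$fp, cmp$predictions)
  expect_equal(cmp$tp + cmp$fn, rep(43L, 6))       # 43 validation meals
})

test_that("per-day reports partition by calendar day", {
  day1 <- t0utc("2023-04-01 08:00:00") + c(0, 4 * 3600)
  day2 <- t0utc("2023-04-02 09:00:00")
  meals <- c(day1, day2)
  preds <- c(day1 + 600)                           # both day-1 meals found
  rep <- dailyReports(preds, meals, 60)
  expect_equal(nrow(rep), 2L)
  expect_equal(rep$meals, c(2L, 1L))
  expect_equal(rep$tp, c(2L, 0L))
  expect_equal(rep$fn, c(0L, 1L))
  # a day with meals but no predictions scores zero by the tp = 0 rule
  expect_equal(rep$ppv[2], 0)
  expect_equal(rep$tpr[2], 0)
  # single-day input equals direct matching
  solo <- dailyReports(preds, day1, 60)
  mc <- matchEvents(preds, day1, 60)
  expect_equal(solo$tp, mc$counts$tp)
  expect_equal(nrow(solo), 1L)
})

test_that("pooled and macro aggregation follow the two conventions", {
  fx <- perDayValidationFixture()
  rows <- fx$days
  rows$scope <- "day"
  rows$ppv <- 0; rows$tpr <- 0; rows$f1 <- 0; rows$f2 <- 0
  for (i in seq_len(nrow(rows))) {
    m <- metricsFor(rows$tp[i], rows$fp[i], rows$fn[i])
    rows[i, c("ppv", "tpr", "f1", "f2")] <- as.list(m)
  }
  macro <- aggregateReports(rows, "macro")
  expect_equal(macro$fp, fx$average[["fp"]])       # printed mean FP 1.7
  expect_equal(round(macro$f2, 2), fx$average[["f2"]])
  pooled <- aggregateReports(rows, "pooled")
  expect_equal(pooled$tp, sum(rows$tp))
  expect_equal(round(pooled$f2, 2),
               round(fBeta(sum(rows$tp), sum(rows$fp), sum(rows$fn), 2), 2))
  # test-split days: macro PPV 0.51 differs from pooled 25/50 = 0.50
  fx6 <- perDayTestFixture()
  rows6 <- fx6$days; rows6$scope <- "day"
  for (i in seq_len(nrow(rows6)))
    rows6[i, c("ppv", "tpr", "f1", "f2")] <-
      as.list(metricsFor(rows6$tp[i], rows6$fp[i], rows6$fn[i]))
  expect_equal(round(aggregateReports(rows6, "macro")$ppv, 2), 0.51)
  expect_equal(aggregateReports(rows6, "pooled")$ppv, 0.50)
  # single report: pooled = macro = itself
  one <- rows[1, ]
  expect_equal(aggregateReports(one, "pooled")$f2,
               aggregateReports(one, "macro")$f2)
  # identical days: macro equals pooled
  same <- rows[c(1, 1, 1), ]
  expect_equal(aggregateReports(same, "macro")$ppv,
               aggregateReports(same, "pooled")$ppv)
  expect_error(aggregateReports(rows[0, ], "pooled"), "no reports")
})
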