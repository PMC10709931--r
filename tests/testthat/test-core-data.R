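test_that("CSV readers build the grid, mark gaps, and report bad rows", {
  cgm <- tempfile(fileext = ".csv"); ev <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,glucose_mg_dl",
               "2023-04-01T08:00:00,110",
               "2023-04-01T08:05:00,115"), cgm)
  writeLines("timestamp,event_type", ev)
  pd <- readParticipant(cgm, ev)
  expect_s4_class(pd, "ParticipantData")
  expect_equal(seriesLength(pd@glucose), 2L)
  expect_false(any(isGap(pd@glucose)))
  expect_equal(nEvents(pd@events), 0L)

  writeLines(c("timestamp,glucose_mg_dl",
               "2023-04-01T08:00:00,110",
               "2023-04-01T08:15:00,140"), cgm)
  gs <- readGlucoseCSV(cgm)
  expect_equal(seriesLength(gs), 4L)
  expect_equal(which(isGap(gs)), c(2L, 3L))   # 08:05 and 08:10 missing

  writeLines(c("timestamp,glucose_mg_dl",
               "2023-04-01T08:00:00,110",
               "2023-04-01T08:05:00,oops"), cgm)
  expect_error(readGlucoseCSV(cgm), "row 2")
  writeLines(c("timestamp,glucose_mg_dl",
               "2023-04-01T08:00:00,110",
               "2023-04-01T08:05:00,-4"), cgm)
  expect_error(readGlucoseCSV(cgm), "out-of-range")
  writeLines(c("timestamp,glucose_mg_dl",
               "2023-04-01T08:05:00,110",
               "2023-04-01T08:00:00,115"), cgm)
  expect_error(readGlucoseCSV(cgm), "increasing")
})

test_that("write/read round trip reproduces timestamps and values exactly", {
  set.seed(11)
  v <- 100 + cumsum(rnorm(50)); v[c(7, 8, 31)] <- NA
  gs <- makeSeries(v)
  ev <- eventLog(t0utc() + c(3600, 7200.0), c("breakfast", "snack"))
  fg <- tempfile(fileext = ".csv"); fe <- tempfile(fileext = ".csv")
  writeGlucoseCSV(gs, fg); writeEventsCSV(ev, fe)
  gs2 <- readGlucoseCSV(fg); ev2 <- readEventsCSV(fe)
  expect_identical(seriesValues(gs2), seriesValues(gs))
  expect_identical(gridTimes(gs2), gridTimes(gs))
  expect_equal(eventTimes(ev2), eventTimes(ev))
  expect_identical(eventTypes(ev2), eventTypes(ev))
})

test_that("events synchronize to the nearest existing reading", {
  gs <- makeSeries(c(110, 115, 120), start = t0utc("2023-04-01 08:00:00"))
  # exact hit on a sample
  ev <- synchronizeEvents(gs, eventLog(t0utc("2023-04-01 08:05:00"), "lunch"))
  expect_equal(eventGridIndex(ev), 2L)
  # 08:02 with samples at 08:00 and 08:05 -> earlier-side nearest, 08:00
  ev <- synchronizeEvents(gs, eventLog(t0utc("2023-04-01 08:02:00"), "lunch"))
  expect_equal(eventGridIndex(ev), 1L)
  # equidistant tie (08:02:30) -> earlier sample
  ev <- synchronizeEvents(gs, eventLog(t0utc("2023-04-01 08:02:30"), "lunch"))
  expect_equal(eventGridIndex(ev), 1L)
  # 08:02 but 08:00 is a gap -> nearest existing reading is 08:05
  gs2 <- makeSeries(c(NA, 115, 120), start = t0utc("2023-04-01 08:00:00"))
  ev <- synchronizeEvents(gs2, eventLog(t0utc("2023-04-01 08:02:00"), "lunch"))
  expect_equal(eventGridIndex(ev), 2L)
  # event far outside the span is flagged and dropped
  expect_warning(
    ev <- synchronizeEvents(gs, eventLog(t0utc("2023-04-01 09:00:00"),
                                         "snack")),
    "dropped")
  expect_equal(nEvents(ev), 0L)
})

test_that("time-span splitting is contiguous, ordered, and exhaustive", {
  perDay <- 288L
  gs <- makeSeries(rep(c(100, 120), length.out = 40 * perDay))
  evTimes <- t0utc() + (seq_len(40) - 0.5) * 86400   # one noon event per day
  ev <- eventLog(evTimes, rep("lunch", 40))
  sp <- splitData(gs, ev, 10)
  expect_equal(seriesLength(splitPart(sp, "train")@glucose), 20L * perDay)
  expect_equal(seriesLength(splitPart(sp, "validation")@glucose), 10L * perDay)
  expect_equal(seriesLength(splitPart(sp, "test")@glucose), 10L * perDay)
  # every sample and event lands in exactly one part
  total <- sum(vapply(c("train", "validation", "test"), function(p)
    seriesLength(splitPart(sp, p)@glucose), integer(1)))
  expect_equal(total, seriesLength(gs))
  expect_equal(nEvents(splitPart(sp, "train")@events), 20L)
  expect_equal(nEvents(splitPart(sp, "validation")@events), 10L)
  expect_equal(nEvents(splitPart(sp, "test")@events), 10L)
  allT <- c(eventTimes(splitPart(sp, "train")@events),
            eventTimes(splitPart(sp, "validation")@events),
            eventTimes(splitPart(sp, "test")@events))
  expect_equal(sort(allT), evTimes)
  # parts are time-ordered and contiguous
  expect_equal(splitPart(sp, "validation")@glucose@startTime,
               t0utc() + 20 * 86400)
  expect_equal(splitPart(sp, "test")@glucose@startTime, t0utc() + 30 * 86400)

  gs12 <- makeSeries(rep(100.0, 12 * perDay))
  sp12 <- splitData(gs12, eventLog(), 3)
  expect_equal(seriesLength(splitPart(sp12, "train")@glucose), 6L * perDay)
  expect_equal(splitPart(sp12, "test")@glucose@startTime, t0utc() + 9 * 86400)

  sp0 <- splitData(gs12, ev, 0)
  expect_equal(seriesLength(splitPart(sp0, "validation")@glucose), 0L)
  expect_equal(seriesLength(splitPart(sp0, "train")@glucose), 12L * perDay)

  expect_error(splitData(gs12, ev, 6), "2 x test span")
})

test_that("subsequence extraction returns windows only when gap-free", {
  v <- c(100, 105, 110, NA, 120, 125, 130)
  gs <- makeSeries(v)
  s <- subsequenceAt(gs, 1, 3)
  expect_equal(s@values, c(100, 105, 110))
  expect_null(subsequenceAt(gs, 3, 3))        # straddles the gap at 4
  expect_equal(subsequenceAt(gs, 5, 3)@values, c(120, 125, 130))  # i = m-n+1
  expect_error(subsequenceAt(gs, 6, 3), "out of range")
  # gap-flag iff the window holds fewer than n present samples
  for (i in 1:5) {
    present <- sum(!is.na(v[i:(i + 2)]))
    expect_identical(is.null(subsequenceAt(gs, i, 3)), present < 3L)
  }
})
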