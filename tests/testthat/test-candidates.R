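test_that("valley search picks suppressed local minima below the cutoff", {
  d <- makeProfile(c(5, 3.5, 3.2, 5, 5, 3.0, 5), n = 24L)
  got <- getValleys(d, dCutoff = 4, valleyWindow = 2)
  expect_equal(got$start_index, c(3L, 6L))
  expect_equal(got$distance, c(3.2, 3.0))
  # the shallower neighbor at index 2 is not a local minimum; with a wider
  # window the better valley wins and suppresses the other
  wide <- getValleys(d, dCutoff = 4, valleyWindow = 4)
  expect_equal(wide$start_index, 6L)
  expect_equal(getValleys(makeProfile(rep(6, 10)), 4, 2)$start_index,
               integer(0))
  one <- getValleys(makeProfile(c(5, 2, 5)), 4, 2)
  expect_equal(one$start_index, 2L)
  # plateau minima take the leftmost index
  plat <- getValleys(makeProfile(c(5, 3, 3, 5)), 4, 1)
  expect_equal(plat$start_index, 2L)
})

test_that("valley suppression invariants hold on random profiles", {
  set.seed(17)
  for (rep in 1:25) {
    vals <- runif(200, 1, 8)
    vals[sample(200, 10)] <- Inf
    d <- makeProfile(vals)
    w <- sample(3:30, 1)
    got <- getValleys(d, dCutoff = 4, valleyWindow = w)
    expect_true(all(got$distance < 4))
    if (nrow(got) > 1)
      expect_true(all(diff(got$start_index) >= w))
    # every candidate is a strict local minimum of the profile
    for (i in got$start_index) {
      lo <- if (i > 1) vals[i - 1] else Inf
      hi <- if (i < 200) vals[i + 1] else Inf
      expect_true(vals[i] < lo && vals[i] < hi)
    }
  }
})

test_that("temporal grouping keeps one minimum-distance representative", {
  cands <- data.frame(
    start_index = c(10L, 16L, 70L),
    start_time = t0utc("2023-04-01 08:00:00") + c(0, 1800, 18000),
    pattern_id = c(1L, 2L, 1L),
    distance = c(3.1, 2.8, 3.5))
  got <- groupCandidates(cands, groupMinutes = 120)
  expect_equal(got$start_index, c(16L, 70L))      # 08:30 and 13:00 survive
  expect_equal(groupCandidates(cands[1, ], 120), cands[1, ])
  apart <- cands; apart$start_time <- t0utc() + c(0, 3, 6) * 7200
  expect_equal(nrow(groupCandidates(apart, 120)), 3L)
  # representatives are members of the input, never synthesized
  expect_true(all(got$start_index %in% cands$start_index))
  expect_lte(nrow(got), nrow(cands))
  # tie on distance: earlier time, then lower pattern id
  tie <- data.frame(start_index = c(5L, 8L), start_time = t0utc() + c(0, 900),
                    pattern_id = c(2L, 1L), distance = c(3, 3))
  expect_equal(groupCandidates(tie, 120)$start_index, 5L)
})

test_that("full selection merges patterns and honors gap exclusion", {
  set.seed(53)
  lib <- defaultKernelLibrary()
  sched <- defaultMealSchedule()[1:2, ]; sched$prob <- 1
  cfg <- simulationConfig(nDays = 3, noiseSd = 2, gapRate = 0,
                          disturbanceRate = 0, mealSchedule = sched,
                          logJitterSd = 0, seed = 53)
  sim <- simulateParticipant(cfg)
  params <- selectionParams()
  tt <- seq(0, 115, by = 5)
  pats <- lapply(1:2, function(i)
    new("ResponsePattern", patternId = as.integer(i),
        values = as.numeric(znormalize(kernelValue(lib[[i]], tt) + 120)),
        provenance = 1L))
  profs <- lapply(pats, function(p) distanceProfile(sim$glucose, p))
  cands <- selectCandidates(sim$glucose, profs, params)
  expect_true(all(cands$distance < params$dCutoff))
  # with both patterns matching the same meals, grouping leaves at most one
  # candidate within the margin of each meal
  for (mt in as.numeric(eventTimes(sim$eventsTrue))) {
    near <- abs(as.numeric(cands$start_time) - mt) <= 3600
    expect_lte(sum(near), 1L)
  }
  # single clean profile reduces to the valley search
  soloP <- selectionParams()
  solo <- selectCandidates(sim$glucose, profs[1], soloP)
  valleys <- getValleys(profs[[1]], soloP$dCutoff,
                        soloP$valleyMinutes / soloP$interval)
  expect_equal(solo$start_index, valleys$start_index)
  # nothing below cutoff anywhere -> empty selection with a warning
  flat <- makeProfile(rep(6, seriesLength(sim$glucose) - 23), n = 24L)
  expect_warning(none <- selectCandidates(sim$glucose, list(flat), params),
                 "no profile value below")
  expect_equal(nrow(none), 0L)
})

test_that("selection finds most injected meals on clean synthetic data", {
  cfg <- simulationConfig(nDays = 7, noiseSd = 3, gapRate = 0,
                          disturbanceRate = 0, logJitterSd = 0, seed = 61)
  sim <- simulateParticipant(cfg)
  params <- selectionParams()
  ev <- synchronizeEvents(sim$glucose, sim$eventsLogged)
  resp <- suppressMessages(extractMealResponses(sim$glucose, ev, params))
  pats <- identifyPatterns(resp, 3)
  profs <- lapply(pats, function(p) distanceProfile(sim$glucose, p))
  cands <- selectCandidates(sim$glucose, profs, params)
  mt <- as.numeric(eventTimes(sim$eventsTrue))
  hit <- vapply(mt, function(t)
    any(abs(as.numeric(cands$start_time) - t) <= 3600), logical(1))
  expect_gte(mean(hit), 0.8)
})

test_that("top-n baseline returns the n best positions per pattern", {
  d <- makeProfile(c(5, 3.5, 3.2, 5, 5, 3.0, 5))
  expect_equal(topNSelect(list(d), 1)$start_index, 6L)
  expect_equal(topNSelect(list(d), 2)$start_index, c(3L, 6L))
  expect_equal(nrow(topNSelect(list(d), 100)), 7L)  # capped at finite count
  withInf <- makeProfile(c(Inf, 3, Inf, 2, Inf))
  expect_equal(topNSelect(list(withInf), 10)$start_index, c(2L, 4L))
  two <- topNSelect(list(makeProfile(1:5, pid = 1L),
                         makeProfile(5:1, pid = 2L)), 1)
  expect_equal(two$pattern_id, c(1L, 2L))
  expect_equal(two$start_index, c(1L, 5L))
})
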