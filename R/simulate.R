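#' Glucose response kernel
#'
#' Parametric shape of a post-meal glucose excursion: an optional brief
#' pre-peak dip, a smooth (half-cosine) rise to `amplitude` at
#' `timeToPeak` minutes, then exponential decay with half-life
#' `decayHalfLife`. The kernel is zero at t = 0 and hard-zeroed beyond
#' 240 minutes, by which point the exponential tail is negligible for
#' realistic shapes.
#'
#' @param amplitude peak excursion above baseline, mg/dl (> 0).
#' @param timeToPeak minutes from meal to peak (> 0).
#' @param decayHalfLife half-life of the post-peak decay, minutes.
#' @param dipDepth optional pre-rise dip depth, mg/dl (0 disables).
#' @param dipTime minutes from meal to the dip minimum.
#' @return A `ResponseKernel` (validated list).
#' @export
responseKernel <- function(amplitude, timeToPeak, decayHalfLife,
                           dipDepth = 0, dipTime = 10) {
  stopifnot(amplitude > 0, timeToPeak > 0, decayHalfLife > 0,
            dipDepth >= 0, dipTime > 0, dipTime < timeToPeak)
  structure(list(amplitude = amplitude, timeToPeak = timeToPeak,
                 decayHalfLife = decayHalfLife, dipDepth = dipDepth,
                 dipTime = dipTime),
            class = "ResponseKernel")
}

#' Evaluate a response kernel
#'
#' @param kernel a [responseKernel()].
#' @param minutes minutes since the meal, `>= 0` (vectorized).
#' @return kernel value(s) in mg/dl.
#' @export
kernelValue <- function(kernel, minutes) {
  if (any(minutes < 0)) stop("minutes since meal must be >= 0")
  k <- kernel
  v <- numeric(length(minutes))
  if (k$dipDepth > 0) {
    dip <- minutes <= k$dipTime
    v[dip] <- -k$dipDepth * (1 - cos(pi * minutes[dip] / k$dipTime)) / 2
    rise <- minutes > k$dipTime & minutes <= k$timeToPeak
    frac <- (minutes[rise] - k$dipTime) / (k$timeToPeak - k$dipTime)
    v[rise] <- -k$dipDepth +
      (k$amplitude + k$dipDepth) * (1 - cos(pi * frac)) / 2
  } else {
    rise <- minutes <= k$timeToPeak
    v[rise] <- k$amplitude * (1 - cos(pi * minutes[rise] / k$timeToPeak)) / 2
  }
  decay <- minutes > k$timeToPeak
  v[decay] <- k$amplitude *
    2^(-(minutes[decay] - k$timeToPeak) / k$decayHalfLife)
  v[minutes > 240] <- 0
  v
}

#' Default kernel library: three distinct response shapes
#'
#' A fast sharp response (snack-like), a medium response with a brief
#' pre-peak dip (bolus-before-meal-like), and a slow large response
#' (mixed-meal-like). Three shapes match the default number of patterns
#' searched for.
#'
#' @return list of three [responseKernel()] objects.
#' @export
defaultKernelLibrary <- function() {
  list(
    responseKernel(amplitude = 60, timeToPeak = 30, decayHalfLife = 35),
    responseKernel(amplitude = 80, timeToPeak = 50, decayHalfLife = 55,
                   dipDepth = 12, dipTime = 15),
    responseKernel(amplitude = 100, timeToPeak = 80, decayHalfLife = 80)
  )
}

#' Default daily meal schedule
#'
#' Three main meals with high logging-independent occurrence probability and
#' an optional afternoon snack, each tied to one kernel shape. Windows are
#' clock-hour ranges within a day.
#'
#' @return data.frame with columns `type`, `startHour`, `endHour`, `prob`,
#'   `kernel`.
#' @export
defaultMealSchedule <- function() {
  data.frame(
    type = c("breakfast", "lunch", "snack", "dinner"),
    startHour = c(6.5, 11.5, 15.0, 17.5),
    endHour = c(9.0, 14.0, 16.5, 20.5),
    prob = c(0.95, 0.95, 0.30, 0.95),
    kernel = c(1L, 2L, 1L, 3L),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defines a synthetic participant: a circadian baseline plus additive meal
#' responses drawn from a small kernel library, Gaussian sensor noise,
#' contiguous sensor-gap runs, and an imperfect event log (missed entries and
#' timestamp jitter).
#'
#' @param nDays number of simulated days (>= 1).
#' @param interval grid spacing, minutes.
#' @param baselineMean mean baseline glucose, mg/dl.
#' @param baselineAmplitude amplitude of the slow circadian sinusoid, mg/dl.
#' @param noiseSd sensor noise standard deviation, mg/dl (>= 0).
#' @param kernelLibrary list of [responseKernel()].
#' @param mealSchedule data.frame as [defaultMealSchedule()].
#' @param disturbanceRate mean number per day of non-meal glucose excursions
#'   (exercise- or stress-like smooth bumps, 20-45 mg/dl over 40-90 min)
#'   that appear in the signal but in neither event log; these emulate the
#'   external factors meal detection must discriminate against.
#' @param gapRate expected fraction of samples removed as gap runs, in [0,1).
#' @param gapRunMean mean gap-run length, samples (geometric).
#' @param missLogProb probability a true meal is absent from the logged
#'   events, in [0,1].
#' @param logJitterSd sd of logged-timestamp jitter, minutes.
#' @param seed integer RNG seed.
#' @return A `SimulationConfig` (validated list).
#' @export
simulationConfig <- function(nDays = 28, interval = 5, baselineMean = 120,
                             baselineAmplitude = 10, noiseSd = 5,
                             kernelLibrary = defaultKernelLibrary(),
                             mealSchedule = defaultMealSchedule(),
                             disturbanceRate = 1,
                             gapRate = 0.02, gapRunMean = 6,
                             missLogProb = 0, logJitterSd = 5,
                             seed = 1L) {
  stopifnot(nDays >= 1, interval > 0, baselineMean > 0,
            baselineAmplitude >= 0, noiseSd >= 0,
            disturbanceRate >= 0,
            gapRate >= 0, gapRate < 1, gapRunMean >= 1,
            missLogProb >= 0, missLogProb <= 1, logJitterSd >= 0,
            length(kernelLibrary) >= 1,
            all(vapply(kernelLibrary, inherits, logical(1), "ResponseKernel")),
            all(mealSchedule$prob >= 0 & mealSchedule$prob <= 1),
            all(mealSchedule$kernel >= 1 &
                  mealSchedule$kernel <= length(kernelLibrary)))
  structure(list(nDays = nDays, interval = interval,
                 baselineMean = baselineMean,
                 baselineAmplitude = baselineAmplitude, noiseSd = noiseSd,
                 kernelLibrary = kernelLibrary, mealSchedule = mealSchedule,
                 disturbanceRate = disturbanceRate,
                 gapRate = gapRate, gapRunMean = gapRunMean,
                 missLogProb = missLogProb, logJitterSd = logJitterSd,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Simulate a synthetic CGM participant
#'
#' Builds the glucose signal as baseline + sum of meal-response kernels +
#' Gaussian noise, clipped to the sensor range `[40, 400]` mg/dl, then
#' removes contiguous gap runs. The logged event log is the true log minus
#' missed entries, with jittered timestamps. Identical seeds give
#' bit-identical outputs.
#'
#' @param cfg a [simulationConfig()].
#' @param startDate first day (`Date` or ISO string); the grid starts at its
#'   midnight UTC.
#' @return list with elements `glucose` ([GlucoseSeries-class]),
#'   `eventsTrue` and `eventsLogged` ([EventLog-class]), and `mealKernels`
#'   (integer kernel index per true meal, for diagnostics).
#' @export
simulateParticipant <- function(cfg, startDate = "2023-03-01") {
  set.seed(cfg$seed)
  step <- cfg$interval * 60
  perDay <- as.integer(round(86400 / step))
  m <- cfg$nDays * perDay
  t0 <- as.POSIXct(paste(startDate, "00:00:00"), tz = "UTC")
  tSec <- (seq_len(m) - 1) * step

  hours <- (tSec / 3600) %% 24
  baseline <- cfg$baselineMean +
    cfg$baselineAmplitude * sin(2 * pi * (hours - 9) / 24)

  # draw meals day by day, in schedule order
  mealSec <- numeric(0)
  mealType <- character(0)
  mealKernel <- integer(0)
  sched <- cfg$mealSchedule
  for (day in seq_len(cfg$nDays) - 1L) {
    for (r in seq_len(nrow(sched))) {
      if (stats::runif(1) > sched$prob[r]) next
      clock <- stats::runif(1, sched$startHour[r], sched$endHour[r])
      sec <- round((day * 24 + clock) * 3600 / step) * step  # snap to grid
      mealSec <- c(mealSec, sec)
      mealType <- c(mealType, sched$type[r])
      mealKernel <- c(mealKernel, sched$kernel[r])
    }
  }
  ord <- order(mealSec)
  mealSec <- mealSec[ord]; mealType <- mealType[ord]
  mealKernel <- mealKernel[ord]

  signal <- baseline
  for (j in seq_along(mealSec)) {
    i0 <- as.integer(mealSec[j] / step) + 1L
    horizon <- min(m, i0 + as.integer(240 / cfg$interval))
    idx <- i0:horizon
    signal[idx] <- signal[idx] +
      kernelValue(cfg$kernelLibrary[[mealKernel[j]]],
                  (idx - i0) * cfg$interval)
  }
  # non-meal disturbances: smooth excursions absent from both event logs
  if (cfg$disturbanceRate > 0) {
    nDist <- stats::rpois(1, cfg$disturbanceRate * cfg$nDays)
    if (nDist > 0) {
      dSec <- round(stats::runif(nDist, 0, m - 1)) * step
      for (j in seq_len(nDist)) {
        amp <- stats::runif(1, 20, 45)
        durMin <- stats::runif(1, 40, 90)
        i0 <- as.integer(dSec[j] / step) + 1L
        horizon <- min(m, i0 + as.integer(ceiling(durMin / cfg$interval)))
        idx <- i0:horizon
        tt <- (idx - i0) * cfg$interval
        signal[idx] <- signal[idx] + amp * sin(pi * pmin(tt / durMin, 1))^2
      }
    }
  }
  if (cfg$noiseSd > 0) signal <- signal + stats::rnorm(m, 0, cfg$noiseSd)
  signal <- pmin(400, pmax(40, signal))

  # contiguous gap runs: starts ~ Bernoulli(gapRate / gapRunMean),
  # lengths ~ Geometric(mean gapRunMean)
  if (cfg$gapRate > 0) {
    pStart <- cfg$gapRate / cfg$gapRunMean
    starts <- which(stats::runif(m) < pStart)
    for (s in starts) {
      len <- 1L + stats::rgeom(1, 1 / cfg$gapRunMean)
      signal[s:min(m, s + len - 1L)] <- NA_real_
    }
  }

  gs <- new("GlucoseSeries", participantId = sprintf("sim-%d", cfg$seed),
            interval = cfg$interval, startTime = t0, values = signal)
  evTrue <- eventLog(t0 + mealSec, mealType)

  kept <- stats::runif(length(mealSec)) >= cfg$missLogProb
  jitter <- if (cfg$logJitterSd > 0)
    stats::rnorm(sum(kept), 0, cfg$logJitterSd * 60) else 0
  loggedSec <- mealSec[kept] + jitter
  ordL <- order(loggedSec)
  evLogged <- eventLog(t0 + loggedSec[ordL], mealType[kept][ordL])

  list(glucose = gs, eventsTrue = evTrue, eventsLogged = evLogged,
       mealKernels = mealKernel)
}
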