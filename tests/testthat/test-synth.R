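dt30 <- 1 / 30

test_that("shape parameter validation rejects invalid waveforms", {
  expect_s3_class(plrShapeParams(), "plrShapeParams")
  expect_error(plrShapeParams(baseline = 0), "baseline")
  expect_error(plrShapeParams(amplitude = -0.1), "amplitude")
  expect_error(plrShapeParams(baseline = 5, amplitude = 5), "amplitude")
  expect_error(plrShapeParams(latency = -1), "latency")
  expect_error(plrShapeParams(timeToPeak = 0), "timeToPeak")
  expect_error(plrShapeParams(redilationTau = 0), "redilationTau")
  expect_error(plrShapeParams(noiseSd = -1), "noiseSd")
  expect_error(plrShapeParams(baseline = NaN), "non-finite")
})

test_that("zero-amplitude noise-free trace is constant at baseline", {
  tr <- simulateTrace(plrShapeParams(baseline = 5.5, amplitude = 0))
  expect_equal(tr$diameter_mm, rep(5.5, nrow(tr)))
  expect_equal(nrow(tr), 4 * 30)
  expect_equal(diff(tr$time_s), rep(dt30, nrow(tr) - 1))
  expect_equal(tr$time_s[1], 0)
})

test_that("noise-free waveform attains its minimum D_b - A at t = L + t_p", {
  sh <- plrShapeParams(baseline = 6, amplitude = 0.9, latency = 0.45,
                       timeToPeak = 0.8)
  tDense <- seq(0, 4, by = 1e-4)
  d <- plrWaveform(tDense, sh, 1)
  expect_equal(min(d), 6 - 0.9, tolerance = 1e-6)
  expect_equal(tDense[which.min(d)], 0.45 + 0.8, tolerance = 1e-3)
  ## percent contraction 15% — a "substantial" (>= 10%) response
  expect_gte(100 * (6 - min(d)) / 6, 10)
  ## waveform is continuous through the redilation switch at t_p
  expect_lt(max(abs(diff(d))), 1e-2)
})

test_that("maximal contraction velocity occurs at L + t_p (1 - sqrt(2)/2)", {
  sh <- plrShapeParams(baseline = 6, amplitude = 0.9, latency = 0.5,
                       timeToPeak = 0.8)
  tDense <- seq(0, 2.5, by = 1e-5)
  d <- plrWaveform(tDense, sh, 1)
  v <- diff(d) / 1e-5
  tMaxV <- tDense[which.min(v)]          # fastest contraction
  expect_equal(tMaxV, 0.5 + 0.8 * (1 - sqrt(2) / 2), tolerance = 1e-3)
})

test_that("generator is deterministic: same config + seed, identical cohort", {
  cfg <- cohortConfig(nSubjects = 6, nFHpos = 3, conditions = "dim_blue",
                      eyes = "right", seed = 99)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(traces(c1), traces(c2))
  expect_identical(subjects(c1), subjects(c2))
  expect_identical(truthParams(c1), truthParams(c2))
  c3 <- simulateCohort(cohortConfig(nSubjects = 6, nFHpos = 3,
                                    conditions = "dim_blue",
                                    eyes = "right", seed = 100))
  expect_false(identical(traces(c1), traces(c3)))
})

test_that("cohort respects the case-control design", {
  ch <- smallCohort()
  subj <- subjects(ch)
  expect_equal(sum(subj$group == "FHpos"), 8L)
  expect_equal(sum(subj$group == "FHneg"), 8L)
  expect_true(all(subj$age_years >= 44 & subj$age_years <= 71))
  tr <- traces(ch)
  expect_setequal(unique(tr$condition),
                  c("dim_red", "dim_blue", "bright_red", "bright_blue"))
  ## 54 targets per dim condition, 4 per bright condition, both eyes
  nTraces <- unique(tr[, c("condition", "eye", "target_index")])
  expect_equal(sum(nTraces$condition == "dim_blue"), 2 * 54)
  expect_equal(sum(nTraces$condition == "bright_blue"), 2 * 4)
  expect_error(cohortConfig(nSubjects = 5, nFHpos = 6), "nFHpos")
  expect_error(cohortConfig(nSubjects = 5, nFHpos = 5), "non-empty")
  expect_error(cohortConfig(effectTargets = 55), "effectTargets")
})

test_that("group latency truths match the configured effect", {
  ch <- effectCohort(seed = 77)
  tru <- truthParams(ch)
  subj <- subjects(ch)
  fhpos <- subj$subject_id[subj$group == "FHpos"]
  atEffect <- tru$target_index %in% c(27, 36)
  isPos <- tru$subject_id %in% fhpos
  mPosEff <- mean(tru$latency[atEffect & isPos])
  mNegEff <- mean(tru$latency[atEffect & !isPos])
  ## LLN: group means of the latency truths within 3 SE of the configured
  ## distributions (SE from the subject-level trait SD)
  sePos <- 0.020 / sqrt(125)
  seNeg <- 0.020 / sqrt(61)
  expect_lt(abs(mPosEff - 0.450), 3 * sePos + 0.010 / sqrt(250))
  expect_lt(abs(mNegEff - 0.477), 3 * seNeg + 0.010 / sqrt(122))
  ## off-target latencies share one distribution across groups
  mPosOff <- mean(tru$latency[!atEffect & isPos])
  mNegOff <- mean(tru$latency[!atEffect & !isPos])
  expect_lt(abs(mPosOff - mNegOff), 4 * 0.020 / sqrt(61))
})

test_that("null configuration injects no group effect", {
  ch <- nullCohort(seed = 5, nSubjects = 40, nFHpos = 20)
  tru <- truthParams(ch)
  subj <- subjects(ch)
  isPos <- tru$subject_id %in% subj$subject_id[subj$group == "FHpos"]
  atEffect <- tru$target_index %in% c(27, 36)
  expect_lt(abs(mean(tru$latency[atEffect & isPos]) -
                mean(tru$latency[atEffect & !isPos])),
            4 * 0.020 / sqrt(20))
})

test_that("missingness injection hits the configured rate and is reproducible", {
  cfg <- cohortConfig(nSubjects = 150, nFHpos = 75, conditions = "dim_blue",
                      eyes = c("right", "left"), blinkRate = 0, seed = 8)
  ch <- simulateCohort(cfg)
  expect_equal(nrow(missingMask(ch)), 0L)
  ch0 <- injectMissingness(ch, rate = 0)
  expect_equal(nrow(missingMask(ch0)), 0L)
  ch1 <- injectMissingness(ch, rate = 0.0076, seed = 3)
  nResp <- 150 * 2 * 54
  frac <- nrow(missingMask(ch1)) / nResp
  se <- sqrt(0.0076 * (1 - 0.0076) / nResp)
  expect_lt(abs(frac - 0.0076), 4 * se)
  ch2 <- injectMissingness(ch, rate = 0.0076, seed = 3)
  expect_identical(missingMask(ch1), missingMask(ch2))
  expect_error(injectMissingness(ch, rate = 1), "rate")
  expect_error(injectMissingness(ch, rate = -0.1), "rate")
})

test_that("blink retest rule: no unmasked gaps inside the first 2.5 s", {
  cfg <- cohortConfig(nSubjects = 10, nFHpos = 5, conditions = "dim_blue",
                      eyes = "right", blinkRate = 0.5, seed = 31)
  ch <- simulateCohort(cfg)
  tr <- data.table::as.data.table(traces(ch))
  gaps <- tr[is.na(tr$diameter_mm)]
  expect_gt(nrow(gaps), 0)            # blinks do occur at this rate
  expect_true(all(gaps$time_s >= 2.5))
  expect_gt(ch@metadata$nRetests, 0)  # early blinks were retested
})
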