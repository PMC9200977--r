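dt30 <- 1 / 30

test_that("the SG matrix operator reproduces signal::sgolayfilt", {
  set.seed(1)
  x <- cumsum(rnorm(120))
  tr <- data.frame(time_s = seq(0, by = dt30, length.out = 120),
                   diameter_mm = x)
  kin <- smoothDifferentiate(tr, window = 7, polyOrder = 2)
  expect_equal(kin$diameter_mm, signal::sgolayfilt(x, 2, 7, 0),
               tolerance = 1e-10)
  expect_equal(kin$velocity_mm_s, signal::sgolayfilt(x, 2, 7, 1, ts = dt30),
               tolerance = 1e-10)
})

test_that("derivatives of elementary traces are exact", {
  t <- seq(0, by = dt30, length.out = 90)
  ## constant: zero velocity and acceleration
  kin <- smoothDifferentiate(data.frame(time_s = t, diameter_mm = rep(5, 90)))
  expect_equal(kin$velocity_mm_s, rep(0, 90), tolerance = 1e-10)
  expect_equal(kin$acceleration_mm_s2, rep(0, 90), tolerance = 1e-10)
  ## linear ramp: constant velocity equal to the slope
  kin <- smoothDifferentiate(data.frame(time_s = t, diameter_mm = 5 - 0.4 * t))
  expect_equal(kin$velocity_mm_s, rep(-0.4, 90), tolerance = 1e-8)
  expect_equal(kin$acceleration_mm_s2, rep(0, 90), tolerance = 1e-8)
})

test_that("missing samples are interpolated and re-flagged; gross gaps rejected", {
  tr <- simulateTrace(plrShapeParams())
  tr$diameter_mm[40:44] <- NA
  kin <- smoothDifferentiate(tr)
  expect_false(anyNA(kin$diameter_mm))
  expect_equal(which(kin$missing), 40:44)
  tr$diameter_mm[1:70] <- NA
  expect_error(smoothDifferentiate(tr), "unusable")
  expect_true(all(is.na(extractParameters(tr))))
})

test_that("onset detection matches the analytic latency and is equivariant", {
  sh1 <- plrShapeParams(baseline = 6, amplitude = 0.9, latency = 0.478,
                        timeToPeak = 0.8)
  f1 <- extractParameters(simulateTrace(sh1))
  expect_lt(abs(f1[["PRL"]] - 0.478), dt30)
  ## +30 ms translation of the latency shifts PRL by +30 ms (within 1 sample)
  sh2 <- plrShapeParams(baseline = 6, amplitude = 0.9, latency = 0.508,
                        timeToPeak = 0.8)
  f2 <- extractParameters(simulateTrace(sh2))
  expect_lt(abs((f2[["PRL"]] - f1[["PRL"]]) - 0.030), dt30)
  ## flat trace: no contraction, onset undefined
  flat <- data.frame(time_s = seq(0, by = dt30, length.out = 120),
                     diameter_mm = rep(5.5, 120))
  expect_true(is.na(detectOnset(smoothDifferentiate(flat))))
  expect_true(all(is.na(extractParameters(flat))))
})

test_that("velocity extrema locations agree with the analytic derivative", {
  ## max |velocity| at L + t_p (1 - sqrt(2)/2) for the pre-peak branch
  for (tp in c(0.6, 0.8, 1.0)) {
    sh <- plrShapeParams(baseline = 6, amplitude = 0.9, latency = 0.5,
                         timeToPeak = tp)
    f <- extractParameters(simulateTrace(sh))
    expect_lt(abs(f[["LMCV"]] - (0.5 + tp * (1 - sqrt(2) / 2))), 1.5 * dt30)
  }
})

test_that("oracle equivalence: PRL, AC, LMP recovered on 100 random noise-free draws", {
  set.seed(5)
  for (r in 1:100) {
    Db <- runif(1, 5, 6.5); A <- runif(1, 0.6, 1.2)
    L <- runif(1, 0.35, 0.6); tp <- runif(1, 0.55, 1.1)
    taur <- runif(1, 0.8, 1.6)
    sh <- plrShapeParams(baseline = Db, amplitude = A, latency = L,
                         timeToPeak = tp, redilationTau = taur)
    f <- extractParameters(simulateTrace(sh))
    expect_lt(abs(f[["PRL"]] - L), dt30)
    expect_lt(abs(f[["AC"]] - A), 1e-3)
    expect_lt(abs(f[["LMP"]] - (L + tp)), dt30)
    expect_equal(f[["PPC"]], 100 * f[["AC"]] / Db, tolerance = 0.2)
  }
})

test_that("noise robustness: median PRL error below 2 samples at sigma = 0.02", {
  set.seed(6)
  errs <- replicate(200, {
    sh <- plrShapeParams(baseline = 5.5, amplitude = 0.9, latency = 0.478,
                         timeToPeak = 0.8, redilationTau = 1.2,
                         noiseSd = 0.02)
    extractParameters(simulateTrace(sh))[["PRL"]] - 0.478
  })
  expect_lt(median(abs(errs), na.rm = TRUE), 2 * dt30)
  expect_lt(mean(is.na(errs)), 0.05)
})

test_that("latency ordering invariants hold on simulated traces", {
  ch <- smallCohort()
  ft <- extractFeatures(ch)
  ok <- !is.na(ft$PRL) & !is.na(ft$LMCV) & !is.na(ft$LMP)
  expect_gt(sum(ok), 1000)
  expect_true(all(ft$PRL[ok] <= ft$LMCV[ok] + 1e-9))
  expect_true(all(ft$LMCV[ok] <= ft$LMP[ok] + dt30 + 1e-9))
  ## contraction kinematics: acceleration peak precedes deceleration peak
  ok2 <- !is.na(ft$LMCA) & !is.na(ft$LMCD)
  expect_true(all(ft$LMCA[ok2] <= ft$LMCD[ok2] + 1e-9))
  ## bounded percentages and non-negative magnitudes
  expect_true(all(ft$PPC >= 0 & ft$PPC <= 100, na.rm = TRUE))
  expect_true(all(ft$PRP >= 0 & ft$PRP <= 100, na.rm = TRUE))
  for (p in c("AC", "MCV", "MCA", "MCD", "MRV", "MRA", "MRD"))
    expect_true(all(ft[[p]] >= 0, na.rm = TRUE))
})

test_that("full recovery yields PRP = 100%", {
  ## fast redilation, long recording: diameter returns to baseline
  sh <- plrShapeParams(baseline = 6, amplitude = 0.9, latency = 0.4,
                       timeToPeak = 0.6, redilationTau = 0.3)
  f <- extractParameters(simulateTrace(sh))
  expect_gte(f[["PRP"]], 99)
})

test_that("extraction on a whole cohort matches single-trace extraction", {
  ch <- smallCohort()
  ft <- extractFeatures(ch)
  tr <- data.table::as.data.table(traces(ch))
  row <- ft[ft$condition == "dim_blue" & ft$eye == "left" &
            !ft$masked, ][3, ]
  one <- tr[tr$subject_id == row$subject_id & tr$eye == "left" &
            tr$condition == "dim_blue" & tr$target_index == row$target_index]
  f1 <- extractParameters(data.frame(time_s = one$time_s,
                                     diameter_mm = one$diameter_mm),
                          stimDuration = 1)
  for (p in plrParameters())
    expect_equal(unname(f1[[p]]), row[[p]], tolerance = 1e-10)
})

test_that("masked responses propagate as all-NA feature rows", {
  ch <- smallCohort()
  ft <- extractFeatures(ch)
  mk <- missingMask(ch)
  expect_equal(sum(ft$masked), nrow(mk))
  masked <- ft[ft$masked, plrParameters()]
  expect_true(all(is.na(as.matrix(masked))))
})
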