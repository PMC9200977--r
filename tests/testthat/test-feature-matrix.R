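test_that("a full cohort yields 136 feature tables with 54/4 columns", {
  ch <- smallCohort()
  ft <- extractFeatures(ch)
  tabs <- buildFeatureTables(ft, subjects(ch))
  expect_length(tabs, 17 * 4 * 2)
  dims <- vapply(tabs, function(t) ncol(featureMatrix(t)), numeric(1))
  expect_true(all(dims[grep("^dim", names(tabs))] == 54))
  expect_true(all(dims[grep("^bright", names(tabs))] == 4))
  t1 <- tabs[["dim_blue|right|PRL"]]
  expect_s4_class(t1, "FeatureTable")
  expect_equal(nrow(featureMatrix(t1)), 16)
  expect_setequal(unique(fhLabels(t1)), c(0L, 1L))
  ## labels align with the subject table
  subj <- subjects(ch)
  expect_equal(unname(fhLabels(t1)[subj$subject_id]),
               as.integer(subj$group == "FHpos"))
  ## right- and left-eye tables hold different measurements
  expect_false(identical(featureMatrix(tabs[["dim_blue|right|PRL"]]),
                         featureMatrix(tabs[["dim_blue|left|PRL"]])))
})

test_that("subjects missing an eye are excluded with a warning", {
  ch <- smallCohort()
  ft <- extractFeatures(ch)
  drop <- ft$subject_id == "S003" & ft$eye == "left"
  expect_warning(tabs <- buildFeatureTables(ft[!drop, ], subjects(ch)),
                 "missing an eye")
  expect_equal(nrow(featureMatrix(tabs[["dim_blue|right|PRL"]])), 15)
  expect_false("S003" %in% rownames(featureMatrix(tabs[[1]])))
})

test_that("masked cells surface as NA in the matching tables", {
  ch <- smallCohort()
  ft <- extractFeatures(ch)
  tabs <- buildFeatureTables(ft, subjects(ch))
  nNA <- sum(vapply(tabs,
                    function(t) sum(is.na(featureMatrix(t))), numeric(1)))
  expect_equal(nNA, 17 * nrow(missingMask(ch)))
})

test_that("mean imputation uses training statistics only", {
  train <- cbind(a = c(1, NA, 3), b = c(4, 5, 6))
  test <- cbind(a = c(NA, 10), b = c(NA, 1))
  out <- imputeMean(train, test)
  expect_equal(unname(out$train[, "a"]), c(1, 2, 3))  # column mean fill
  expect_equal(unname(out$test[1, "a"]), 2)           # training mean, not 10
  expect_equal(unname(out$test[1, "b"]), 5)
  expect_equal(out$nImputed, 3L)
  ## no missing cells: identity
  clean <- imputeMean(out$train)
  expect_identical(clean$train, out$train)
  expect_equal(clean$nImputed, 0L)
  ## all-missing column dropped with a warning
  expect_warning(dropped <- imputeMean(cbind(a = c(NA_real_, NA_real_),
                                             b = c(1, 2))),
                 "all-missing")
  expect_equal(colnames(dropped$train), "b")
})

test_that("min-max scaling maps to [0, 1] with clipping and 0.5 constants", {
  train <- cbind(a = c(2, 4, 6), b = c(7, 7, 7))
  test <- cbind(a = c(8, 0, 3), b = c(9, 7, 5))
  out <- minmaxScale(train, test)
  expect_equal(unname(out$train[, "a"]), c(0, 0.5, 1))
  expect_equal(unname(out$train[, "b"]), c(0.5, 0.5, 0.5))
  expect_equal(unname(out$test[, "a"]), c(1, 0, 0.25))  # clipped at 1 and 0
  expect_equal(unname(out$test[, "b"]), c(0.5, 0.5, 0.5))
})

test_that("train = test = full data reproduces a single global scaling", {
  ch <- smallCohort()
  X <- featureMatrix(prlTable(ch))
  pp <- pupilperim:::.preprocessFold(X, X)
  expect_identical(pp$train, pp$test)
  expect_true(all(pp$train >= 0 & pp$train <= 1))
  expect_false(anyNA(pp$train))
})
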