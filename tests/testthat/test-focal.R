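test_that("target selection applies a strict threshold in weight order", {
  map <- setNames(rep(0.001, 54), paste0("T", 1:54))
  map["T27"] <- 0.50
  map["T36"] <- 0.48
  map <- map / sum(map)
  sel <- selectDiscriminativeTargets(map, threshold = 0.40)
  expect_equal(sel, c(27L, 36L))          # descending weight order
  expect_length(selectDiscriminativeTargets(map, threshold = 1.0), 0)
  uniform <- setNames(rep(1 / 54, 54), paste0("T", 1:54))
  expect_length(selectDiscriminativeTargets(uniform, threshold = 0.47), 0)
  expect_equal(selectDiscriminativeTargets(map, top = 2), c(27L, 36L))
})

test_that("pooled t-test matches the hand-computed statistic", {
  cg <- compareGroups(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(cg$diff, -3)
  expect_equal(cg$t, -3 / sqrt(1 * (1 / 3 + 1 / 3)), tolerance = 1e-6)
  expect_equal(cg$df, 4)
  expect_equal(cg$p, 2 * pt(-3.6742, 4), tolerance = 1e-4)
  expect_equal(cg$groups$mean, c(5, 2))
  expect_equal(cg$groups$se, c(1, 1) / sqrt(3), tolerance = 1e-9)
  ## identical constant groups: zero difference, p = 1
  same <- compareGroups(rep(2, 8), rep(c(0, 1), 4))
  expect_equal(same$diff, 0)
  expect_equal(same$p, 1)
  expect_error(compareGroups(1:3, c(0, 1, 1)), ">= 2 subjects")
})

test_that("age adjustment recovers unadjusted results for orthogonal ages", {
  set.seed(21)
  labels <- rep(c(0, 1), each = 40)
  values <- 0.47 - 0.03 * labels + rnorm(80, 0, 0.02)
  ages <- rnorm(80, 60, 5)                 # independent of group and value
  un <- compareGroups(values, labels)
  ad <- ageAdjustedComparison(values, labels, ages)
  expect_equal(ad$groups$mean, un$groups$mean, tolerance = 0.01)
  expect_equal(ad$diff, un$diff, tolerance = 0.01)
  expect_lt(ad$p, 0.001)
})

test_that("a pure age effect yields a null adjusted group difference", {
  set.seed(22)
  labels <- rep(c(0, 1), each = 40)
  ages <- rnorm(80, 60, 5)
  values <- 0.2 + 0.004 * ages + rnorm(80, 0, 1e-4)
  ad <- ageAdjustedComparison(values, labels, ages)
  expect_gt(ad$p, 0.2)
  expect_lt(abs(ad$diff), 1e-4)
})

test_that("age confounding is removed by the linear model", {
  set.seed(23)
  labels <- rep(c(1, 0), each = 50)
  ages <- ifelse(labels == 1, rnorm(100, 55, 3), rnorm(100, 65, 3))
  values <- 0.3 + 0.005 * ages + rnorm(100, 0, 0.005)  # age-only effect
  un <- compareGroups(values, labels)
  ad <- ageAdjustedComparison(values, labels, ages)
  expect_lt(un$p, 1e-4)                    # spurious unadjusted difference
  expect_gt(ad$p, 0.05)                    # gone after adjustment
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.019, 1), 0.019)
  expect_equal(bonferroni(0.019, 2), 0.038)
  expect_equal(bonferroni(0.8, 2), 1)
  expect_equal(bonferroni(c(0.01, 0.4)), c(0.02, 0.8))
  expect_error(bonferroni(0.05, 0), "m must be")
  p <- runif(10)
  expect_true(all(bonferroni(p, 3) >= p))
})

test_that("focal analysis flags the injected latency effect", {
  ch <- effectCohort(seed = 31)
  tab <- prlTable(ch)
  br <- bootstrapAUC(tab, B = 100, rounds = 50, seed = 32)
  fa <- focalAnalysis(tab, br, top = 2)
  expect_setequal(fa$targets, c(27L, 36L))
  expect_equal(fa$m, 2L)
  cmp <- fa$comparison
  expect_equal(nrow(cmp), 4L)              # 2 models x 2 groups
  ## FH+ faster than FH- in both models, significant after correction
  for (mod in c("unadjusted", "age_adjusted")) {
    rows <- cmp[cmp$model == mod, ]
    expect_lt(rows$mean[rows$group == "FHpos"],
              rows$mean[rows$group == "FHneg"])
    expect_true(all(rows$p_bonferroni <= 1))
    expect_true(all(rows$significant))
    expect_equal(rows$p_bonferroni, pmin(1, rows$p * 2))
  }
  ## threshold selection may be empty on a diffuse map — returns NULL
  diffuse <- br
  diffuse@weightMap[] <- 1 / length(diffuse@weightMap)
  expect_message(out <- focalAnalysis(tab, diffuse, threshold = 0.47),
                 "no target")
  expect_null(out)
})
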