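test_that("a perfectly separating feature is learned in one round", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  m <- trainAdaBoost(x, y, rounds = 10)
  expect_equal(nrow(stumps(m)), 1L)          # early stop at zero error
  expect_equal(sign(predictScore(m, x)), ifelse(y == 1, 1, -1))
  expect_equal(sum(featureWeights(m)), 1)
})

test_that("feature weights are a distribution over the training features", {
  set.seed(3)
  x <- matrix(rnorm(40 * 6), 40, 6,
              dimnames = list(NULL, paste0("T", 1:6)))
  y <- rep(c(0, 1), 20)
  m <- trainAdaBoost(x, y, rounds = 25)
  w <- featureWeights(m)
  expect_length(w, 6)
  expect_named(w, paste0("T", 1:6))
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1)
  expect_lte(nrow(stumps(m)), 25)
})

test_that("boosting beats a single stump on an inseparable 1-D toy set", {
  ## one point breaks linear separability; exhaustive stump search is the
  ## oracle for the best single-threshold accuracy
  x <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  y <- c(0, 0, 1, 0, 1, 1)
  thrs <- c(0.5, seq(1.5, 6.5, by = 1))
  stumpAcc <- max(vapply(thrs, function(th) {
    max(mean((x[, 1] > th) == y), mean((x[, 1] <= th) == y))
  }, numeric(1)))
  m <- trainAdaBoost(x, y, rounds = 3)
  ensAcc <- mean((predictScore(m, x) > 0) == y)
  expect_gte(ensAcc, stumpAcc)
})

test_that("compiled AdaBoost matches the plain-R reference implementation", {
  set.seed(11)
  for (r in 1:5) {
    x <- matrix(round(rnorm(18 * 3), 2), 18, 3)
    y <- rep(c(0L, 1L), 9)
    m <- trainAdaBoost(x, y, rounds = 8)
    ref <- refAdaBoost(x, y, rounds = 8)
    expect_equal(stumps(m)$feature, ref$feature)
    expect_equal(stumps(m)$threshold, ref$threshold)
    expect_equal(stumps(m)$polarity, ref$polarity)
    expect_equal(stumps(m)$alpha, ref$alpha, tolerance = 1e-10)
  }
})

test_that("degenerate training inputs are rejected", {
  x <- matrix(rnorm(10), ncol = 1)
  expect_error(trainAdaBoost(x, rep(1, 10)), "single-class")
  expect_error(trainAdaBoost(x, c(rep(0, 9), 2)), "binary")
  x[3] <- NA
  expect_error(trainAdaBoost(x, rep(c(0, 1), 5)), "missing")
})

test_that("scoring honours column alignment and empty models", {
  set.seed(4)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("T", 1:4)))
  y <- rep(c(0, 1), 15)
  m <- trainAdaBoost(x, y, rounds = 10)
  ## permuting named columns is undone by the alignment map
  perm <- x[, c(3, 1, 4, 2)]
  expect_equal(predictScore(m, perm), predictScore(m, x))
  expect_error(predictScore(m, x[, 1:3]), "missing training feature")
  ## constant features produce no usable stump: empty model, zero scores
  const <- matrix(1, 10, 2)
  m0 <- trainAdaBoost(const, rep(c(0, 1), 5), rounds = 5)
  expect_equal(nrow(stumps(m0)), 0L)
  expect_equal(predictScore(m0, const), rep(0, 10))
})

test_that("AUC equals pairwise concordance with ties counted half", {
  expect_equal(aucROC(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(aucROC(c(5, 6, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(aucROC(rep(2, 6), rep(c(0, 1), 3)), 0.5)
  expect_warning(bad <- aucROC(1:3, c(1, 1, 1)), "one class")
  expect_true(is.na(bad))
  ## brute-force oracle and pROC cross-check on random data
  set.seed(9)
  for (r in 1:20) {
    sc <- round(rnorm(30), 1)            # rounded: ties occur
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    a <- aucROC(sc, y)
    expect_equal(a, refAUC(sc, y))
    if (requireNamespace("pROC", quietly = TRUE))
      expect_equal(a, as.numeric(pROC::auc(y, sc, quiet = TRUE,
                                           direction = "<")),
                   tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(10)
  sc <- rnorm(40)
  y <- rbinom(40, 1, 0.5)
  a <- aucROC(sc, y)
  expect_equal(aucROC(exp(sc), y), a)
  expect_equal(aucROC(3 * sc - 7, y), a)
  expect_equal(aucROC(atan(sc), y), a)
})
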