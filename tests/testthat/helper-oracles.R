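## Independent reference implementations and shared fixtures.

## Plain-R discrete AdaBoost: exhaustive stump search, same tie-break rules
## (lowest feature, lowest threshold, polarity +1 preferred). Used as the
## independent oracle for the compiled implementation.
refAdaBoost <- function(X, y, rounds) {
  n <- nrow(X)
  y1 <- ifelse(y == 1, 1, -1)
  w <- rep(1 / n, n)
  stumps <- NULL
  for (t in seq_len(rounds)) {
    best <- list(err = Inf)
    for (j in seq_len(ncol(X))) {
      xs <- sort(unique(X[, j]))
      thrs <- c(xs[1] - 1,
                if (length(xs) > 1) (head(xs, -1) + tail(xs, -1)) / 2)
      for (thr in thrs) {
        predPos <- ifelse(X[, j] > thr, 1, -1)
        e1 <- sum(w[predPos != y1])
        for (pol in c(1, -1)) {
          err <- if (pol == 1) e1 else 1 - e1
          if (err < best$err - 1e-12)
            best <- list(err = err, j = j, thr = thr, pol = pol,
                         pred = pol * predPos)
        }
      }
    }
    if (best$err >= 0.5 - 1e-12) break
    eps <- max(best$err, 1e-12)
    alpha <- 0.5 * log((1 - eps) / eps)
    stumps <- rbind(stumps,
                    data.frame(feature = best$j, threshold = best$thr,
                               polarity = best$pol, alpha = alpha))
    w <- w * exp(-alpha * y1 * best$pred)
    w <- w / sum(w)
    if (best$err <= 1e-12) break
  }
  stumps
}

## brute-force AUC over all positive-negative pairs (ties = 1/2)
refAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

## shared small cohorts, built once per test run
.fixtures <- new.env()

smallCohort <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- cohortConfig(nSubjects = 16, nFHpos = 8, seed = 2)
    .fixtures$small <- injectMissingness(simulateCohort(cfg))
  }
  .fixtures$small
}

smallPipeline <- function() {
  if (is.null(.fixtures$pipe)) {
    rc <- runConfig(cohort = cohortConfig(nSubjects = 16, nFHpos = 8,
                                          seed = 2),
                    replicates = 5, rounds = 10, seed = 4)
    .fixtures$pipe <- suppressMessages(runPipeline(rc))
  }
  .fixtures$pipe
}

## dim-blue right-eye effect cohort at the reference case-control design
effectCohort <- function(seed = 421, ...) {
  cfg <- cohortConfig(conditions = "dim_blue", eyes = "right", seed = seed,
                      ...)
  simulateCohort(cfg)
}

nullCohort <- function(seed, nSubjects = 80, nFHpos = 40) {
  cfg <- cohortConfig(nSubjects = nSubjects, nFHpos = nFHpos,
                      conditions = "dim_blue", eyes = "right",
                      latencyFHpos = 0.477, latencyFHneg = 0.477,
                      seed = seed)
  simulateCohort(cfg)
}

## feature table for the dim-blue right-eye PRL model of a cohort
prlTable <- function(cohort) {
  ft <- extractFeatures(cohort)
  tabs <- buildFeatureTables(ft, subjects(cohort))
  tabs[["dim_blue|right|PRL"]]
}
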