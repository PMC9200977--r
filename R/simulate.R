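## Synthetic cohort generator.
##
## The noise-free transient PLR model for a trace with baseline diameter
## D_b, latency L, contraction amplitude A, time-to-peak t_p and redilation
## time constant tau_r is
##
##   D(t) = D_b - A * s(u) * r(u) - g(u),     u = t - L
##   s(u) = (u/t_p)^2 * exp(2 * (1 - u/t_p))  for u >= 0, else 0
##   r(u) = exp(-max(0, u - t_p) / tau_r)
##
## s() is a gamma-shaped contraction kernel: smooth onset with zero initial
## velocity, peak value exactly 1 at u = t_p, and analytically tractable
## velocity/acceleration extrema (maximal contraction velocity at
## u = t_p * (1 - sqrt(2)/2)). r() multiplies in exponential redilation
## after the peak; it equals 1 at u = t_p so the waveform is continuous.
## Bright stimuli add a sustained (melanopsin-like) component
## g(u) = A_s * (1 - exp(-u/tau_s)) during the stimulus, decaying with a
## slower time constant (3 * tau_s) after light offset.

.truncnorm <- function(n, mean, sd, lo, hi) {
  ## inverse-CDF sampling: vectorised, one uniform per draw (deterministic
  ## draw count keeps cohort generation bit-reproducible)
  if (sd <= 0) return(rep(mean, n))
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

#' @importFrom stats pnorm qnorm rbinom
NULL

#' PLR waveform shape parameters
#'
#' Validated parameter set for the generative transient/sustained PLR
#' waveform model (see [simulateTrace()]).
#'
#' @param baseline baseline pupil diameter D_b (mm), > 0
#' @param latency response latency L (s), >= 0
#' @param amplitude transient contraction amplitude A (mm), 0 <= A < D_b
#' @param timeToPeak time from response onset to maximal contraction t_p
#'   (s), > 0
#' @param redilationTau redilation time constant tau_r (s), > 0
#' @param sustainedAmplitude sustained (melanopsin-driven) amplitude A_s
#'   (mm), >= 0; 0 for dim stimuli
#' @param sustainedTau sustained-component time constant tau_s (s), > 0
#' @param noiseSd per-sample Gaussian measurement noise SD (mm), >= 0
#' @return named list of class `plrShapeParams`
#' @export
plrShapeParams <- function(baseline = 5.5, latency = 0.45, amplitude = 0.9,
                           timeToPeak = 0.8, redilationTau = 1.2,
                           sustainedAmplitude = 0, sustainedTau = 1.5,
                           noiseSd = 0) {
  p <- list(baseline = baseline, latency = latency, amplitude = amplitude,
            timeToPeak = timeToPeak, redilationTau = redilationTau,
            sustainedAmplitude = sustainedAmplitude,
            sustainedTau = sustainedTau, noiseSd = noiseSd)
  bad <- !is.finite(unlist(p))
  if (any(bad))
    stop("non-finite shape parameter(s): ",
         paste(names(p)[bad], collapse = ", "))
  if (baseline <= 0) stop("baseline diameter must be > 0")
  if (amplitude < 0 || amplitude >= baseline)
    stop("amplitude must satisfy 0 <= A < baseline")
  if (latency < 0) stop("latency must be >= 0")
  if (timeToPeak <= 0) stop("timeToPeak must be > 0")
  if (redilationTau <= 0) stop("redilationTau must be > 0")
  if (sustainedAmplitude < 0) stop("sustainedAmplitude must be >= 0")
  if (sustainedTau <= 0) stop("sustainedTau must be > 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  structure(p, class = "plrShapeParams")
}

#' Noise-free PLR waveform
#'
#' Evaluates the closed-form generative pupil-diameter model at arbitrary
#' times; the independent analytic reference for the feature extractor.
#'
#' @param t times (s) from stimulus onset
#' @param shape a [plrShapeParams()] object (its `noiseSd` is ignored)
#' @param stimDuration stimulus duration (s); governs sustained-component
#'   offset decay
#' @return pupil diameter (mm) at `t`
#' @export
plrWaveform <- function(t, shape, stimDuration = 1) {
  u <- t - shape$latency
  rho <- u / shape$timeToPeak
  s <- ifelse(u > 0, rho^2 * exp(2 * (1 - rho)), 0)
  r <- exp(-pmax(0, u - shape$timeToPeak) / shape$redilationTau)
  g <- 0
  if (shape$sustainedAmplitude > 0) {
    As <- shape$sustainedAmplitude
    ts <- shape$sustainedTau
    gOn <- As * (1 - exp(-pmax(0, pmin(u, stimDuration)) / ts))
    gPeak <- As * (1 - exp(-stimDuration / ts))
    g <- ifelse(u <= stimDuration, gOn,
                gPeak * exp(-(u - stimDuration) / (3 * ts)))
  }
  shape$baseline - shape$amplitude * s * r - g
}

#' Simulate a single pupil trace
#'
#' Samples the PLR waveform model on a uniform time grid starting at the
#' stimulus onset (t = 0) and adds per-sample Gaussian noise.
#'
#' @param shape a [plrShapeParams()] object
#' @param spec a [stimulusSpec()] (sets stimulus and recording duration)
#' @param samplingRate samples per second (Hz)
#' @param seed optional integer seed for the noise draw
#' @return `data.frame` with columns `time_s`, `diameter_mm`; the generating
#'   parameters are attached as attribute `"truth"` and the condition as
#'   `"condition"`
#' @examples
#' tr <- simulateTrace(plrShapeParams(amplitude = 0.9, baseline = 6))
#' min(tr$diameter_mm)  # ~5.1 at t = latency + timeToPeak
#' @export
simulateTrace <- function(shape, spec = stimulusSpec("dim_blue"),
                          samplingRate = 30, seed = NULL) {
  if (!inherits(shape, "plrShapeParams"))
    shape <- do.call(plrShapeParams, shape)
  if (!is.null(seed)) set.seed(seed)
  n <- round(spec$record_duration_s * samplingRate)
  t <- seq(0, by = 1 / samplingRate, length.out = n)
  d <- plrWaveform(t, shape, spec$stim_duration_s)
  if (shape$noiseSd > 0) d <- d + rnorm(n, 0, shape$noiseSd)
  out <- data.frame(time_s = t, diameter_mm = d)
  attr(out, "truth") <- shape
  attr(out, "condition") <- spec$condition
  out
}

#' Cohort simulation configuration
#'
#' Study-design defaults follow the chromatic pupilloperimetry case-control
#' design this package models: 186 subjects (125 FH+, 61 FH-), group ages
#' ~N(59.9, 6.7) / N(59.1, 5.6) truncated to 44-71 years, and a focal
#' latency effect at two peripheral temporal-field targets of the right eye
#' under dim blue light (FH+ 0.450 s vs FH- 0.477 s). Noise and
#' between-subject dispersion defaults are documented in the package
#' vignette.
#'
#' @param nSubjects total cohort size
#' @param nFHpos number of family-history-positive subjects
#' @param conditions stimulus conditions to simulate
#' @param eyes eyes to simulate
#' @param effectTargets grid indices carrying the group latency effect
#' @param effectConditions,effectEyes conditions/eyes in which the effect is
#'   injected
#' @param latencyFHpos,latencyFHneg group mean latency (s) at effect
#'   targets; all other targets use `latencyFHneg` for both groups
#' @param betweenSubjectSd SD (s) of the per-subject latency trait shared
#'   across targets
#' @param targetJitterSd SD (s) of independent per-target latency jitter
#' @param noiseSd per-sample diameter noise SD (mm)
#' @param missingnessRate fraction of (subject, eye, condition, target)
#'   responses flagged missing at the feature level (see
#'   [injectMissingness()])
#' @param samplingRate camera sampling rate (Hz)
#' @param blinkRate fraction of traces receiving a blink gap; blinks within
#'   the first 2.5 s trigger an automatic retest (the trace is regenerated)
#' @param seed integer seed; identical config + seed gives bit-identical
#'   cohorts
#' @return validated config list of class `cohortConfig`
#' @export
cohortConfig <- function(nSubjects = 186L, nFHpos = 125L,
                         conditions = .CONDITIONS, eyes = .EYES,
                         effectTargets = c(27L, 36L),
                         effectConditions = "dim_blue",
                         effectEyes = "right",
                         latencyFHpos = 0.450, latencyFHneg = 0.477,
                         betweenSubjectSd = 0.020, targetJitterSd = 0.010,
                         noiseSd = 0.010, missingnessRate = 0.0076,
                         samplingRate = 30, blinkRate = 0.05, seed = 1L) {
  conditions <- match.arg(conditions, .CONDITIONS, several.ok = TRUE)
  eyes <- match.arg(eyes, .EYES, several.ok = TRUE)
  cfg <- list(nSubjects = as.integer(nSubjects), nFHpos = as.integer(nFHpos),
              conditions = conditions, eyes = eyes,
              effectTargets = as.integer(effectTargets),
              effectConditions = effectConditions, effectEyes = effectEyes,
              latencyFHpos = latencyFHpos, latencyFHneg = latencyFHneg,
              betweenSubjectSd = betweenSubjectSd,
              targetJitterSd = targetJitterSd, noiseSd = noiseSd,
              missingnessRate = missingnessRate,
              samplingRate = samplingRate, blinkRate = blinkRate,
              seed = as.integer(seed))
  if (cfg$nFHpos > cfg$nSubjects)
    stop("nFHpos must be <= nSubjects")
  if (cfg$nFHpos < 1L || cfg$nSubjects - cfg$nFHpos < 1L)
    stop("both FH+ and FH- groups must be non-empty")
  if (cfg$missingnessRate < 0 || cfg$missingnessRate >= 1)
    stop("missingnessRate must be in [0, 1)")
  if (length(cfg$effectTargets) &&
      !all(cfg$effectTargets %in% 1:54))
    stop("effectTargets must be grid indices in 1..54")
  if (cfg$samplingRate <= 0) stop("samplingRate must be > 0")
  structure(cfg, class = "cohortConfig")
}

## per-condition waveform shape distributions (trace-level draws)
.shapeDefaults <- function(condition) {
  if (grepl("^bright", condition)) {
    list(A = c(1.6, 0.12, 1.0, 2.2), tp = c(1.1, 0.06, 0.8, 1.5),
         taur = c(3.0, 0.20, 2.0, 4.0),
         As = if (condition == "bright_blue") c(0.50, 0.05, 0.3, 0.7)
              else c(0.15, 0.03, 0.05, 0.3),
         taus = 1.5)
  } else {
    list(A = c(0.90, 0.08, 0.40, 1.50), tp = c(0.80, 0.04, 0.55, 1.10),
         taur = c(1.2, 0.10, 0.8, 1.6), As = c(0, 0, 0, 0), taus = 1.5)
  }
}

#' Simulate a chromatic pupilloperimetry cohort
#'
#' Draws a synthetic case-control cohort of pupil traces with known ground
#' truth. Each subject carries a latency trait (shared across targets);
#' FH+ subjects additionally receive the configured focal latency shift at
#' `effectTargets` in `effectConditions`/`effectEyes`. Blink gaps are
#' injected at random; traces with a gap inside the first 2.5 s are
#' automatically regenerated ("retested") and counted in the metadata.
#'
#' @param config a [cohortConfig()]
#' @return a \linkS4class{PupilCohort}
#' @examples
#' cohort <- simulateCohort(cohortConfig(nSubjects = 6, nFHpos = 3,
#'   conditions = "dim_blue", eyes = "right", seed = 7))
#' cohort
#' @export
simulateCohort <- function(config = cohortConfig()) {
  if (!inherits(config, "cohortConfig")) config <- do.call(cohortConfig, config)
  set.seed(config$seed)
  n <- config$nSubjects
  nPos <- config$nFHpos
  ids <- sprintf("S%03d", seq_len(n))
  group <- rep(c("FHpos", "FHneg"), c(nPos, n - nPos))

  age <- numeric(n)
  age[group == "FHpos"] <- .truncnorm(nPos, 59.93, 6.69, 44, 71)
  age[group == "FHneg"] <- .truncnorm(n - nPos, 59.08, 5.56, 44, 71)
  sex <- ifelse(rbinom(n, 1, ifelse(group == "FHpos", 0.60, 0.74)) == 1,
                "F", "M")
  subjectsTab <- data.frame(subject_id = ids, group = group,
                            age_years = round(age, 1), sex = sex,
                            stringsAsFactors = FALSE)

  Db <- .truncnorm(n, 5.5, 0.4, 4.5, 7.0)        # per-subject baseline
  subjOffset <- rnorm(n, 0, config$betweenSubjectSd)

  dt <- 1 / config$samplingRate
  traceList <- list()
  truthList <- list()
  nRetests <- 0L

  for (cond in config$conditions) {
    spec <- stimulusSpec(cond)
    sh <- .shapeDefaults(cond)
    nt <- round(spec$record_duration_s * config$samplingRate)
    tGrid <- seq(0, by = dt, length.out = nt)
    targets <- spec$targets
    m <- n * length(targets)
    for (eye in config$eyes) {
      subjIdx <- rep(seq_len(n), each = length(targets))
      targIdx <- rep(targets, times = n)

      A <- .truncnorm(m, sh$A[1], sh$A[2], sh$A[3], sh$A[4])
      tp <- .truncnorm(m, sh$tp[1], sh$tp[2], sh$tp[3], sh$tp[4])
      taur <- .truncnorm(m, sh$taur[1], sh$taur[2], sh$taur[3], sh$taur[4])
      As <- if (sh$As[1] > 0)
        .truncnorm(m, sh$As[1], sh$As[2], sh$As[3], sh$As[4]) else rep(0, m)
      jit <- rnorm(m, 0, config$targetJitterSd)

      L <- config$latencyFHneg + subjOffset[subjIdx] + jit
      if (cond %in% config$effectConditions && eye %in% config$effectEyes &&
          length(config$effectTargets)) {
        hit <- group[subjIdx] == "FHpos" &
          targIdx %in% config$effectTargets
        L[hit] <- L[hit] + (config$latencyFHpos - config$latencyFHneg)
      }
      L <- pmin(pmax(L, 0.30), 0.65)

      ## waveform matrix: rows = time, columns = traces
      U <- outer(tGrid, L, "-")
      TP <- matrix(tp, nt, m, byrow = TRUE)
      RHO <- U / TP
      S <- ifelse(U > 0, RHO^2 * exp(2 * (1 - RHO)), 0)
      R <- exp(-pmax(0, U - TP) / matrix(taur, nt, m, byrow = TRUE))
      D <- matrix(Db[subjIdx], nt, m, byrow = TRUE) -
        matrix(A, nt, m, byrow = TRUE) * S * R
      if (any(As > 0)) {
        ASM <- matrix(As, nt, m, byrow = TRUE)
        gOn <- ASM * (1 - exp(-pmax(0, pmin(U, spec$stim_duration_s)) /
                                sh$taus))
        gPk <- ASM * (1 - exp(-spec$stim_duration_s / sh$taus))
        D <- D - ifelse(U <= spec$stim_duration_s, gOn,
                        gPk * exp(-(U - spec$stim_duration_s) /
                                    (3 * sh$taus)))
      }
      D <- D + matrix(rnorm(nt * m, 0, config$noiseSd), nt, m)

      ## blink gaps; early blinks (first 2.5 s) are retested: the trace is
      ## regenerated with fresh noise and no blink, as after a clean retest
      if (config$blinkRate > 0) {
        blink <- runif(m) < config$blinkRate
        gapStart <- runif(m, 0.2, spec$record_duration_s - 0.4)
        gapLen <- runif(m, 0.10, 0.25)
        retest <- blink & gapStart < 2.5
        nRetests <- nRetests + sum(retest)
        if (any(retest)) {
          idx <- which(retest)
          base <- matrix(Db[subjIdx[idx]], nt, length(idx), byrow = TRUE) -
            matrix(A[idx], nt, length(idx), byrow = TRUE) *
            S[, idx, drop = FALSE] * R[, idx, drop = FALSE]
          if (any(As > 0)) {
            Ui <- U[, idx, drop = FALSE]
            ASi <- matrix(As[idx], nt, length(idx), byrow = TRUE)
            gOn <- ASi * (1 - exp(-pmax(0, pmin(Ui, spec$stim_duration_s)) /
                                    sh$taus))
            gPk <- ASi * (1 - exp(-spec$stim_duration_s / sh$taus))
            base <- base - ifelse(Ui <= spec$stim_duration_s, gOn,
                                  gPk * exp(-(Ui - spec$stim_duration_s) /
                                              (3 * sh$taus)))
          }
          D[, idx] <- base +
            matrix(rnorm(nt * length(idx), 0, config$noiseSd), nt)
        }
        keepBlink <- which(blink & !retest)
        for (k in keepBlink) {
          i0 <- max(1L, round(gapStart[k] / dt))
          i1 <- min(nt, i0 + round(gapLen[k] / dt))
          D[i0:i1, k] <- NA_real_
        }
      }

      traceList[[paste(cond, eye)]] <- data.table::data.table(
        subject_id = rep(ids[subjIdx], each = nt),
        eye = eye, condition = cond,
        target_index = rep(targIdx, each = nt),
        time_s = rep(tGrid, times = m),
        diameter_mm = as.vector(D))
      truthList[[paste(cond, eye)]] <- data.table::data.table(
        subject_id = ids[subjIdx], eye = eye, condition = cond,
        target_index = targIdx, baseline = Db[subjIdx], latency = L,
        amplitude = A, timeToPeak = tp, redilationTau = taur,
        sustainedAmplitude = As, sustainedTau = sh$taus)
    }
  }

  cohort <- new("PupilCohort",
                traces = data.table::rbindlist(traceList),
                subjects = subjectsTab,
                truth = as.data.frame(data.table::rbindlist(truthList)),
                mask = data.frame(subject_id = character(),
                                  eye = character(), condition = character(),
                                  target_index = integer()),
                metadata = list(config = unclass(config),
                                seed = config$seed, nRetests = nRetests))
  validObject(cohort)
  cohort
}

#' Flag responses as missing at the feature level
#'
#' Marks whole (subject, eye, condition, target) responses as missing
#' uniformly at random; the mask is honoured by [extractFeatures()], which
#' emits NA for all 17 parameters of a masked response, and the resulting
#' feature-matrix cells are later mean-imputed. This emulates the
#' missing-data process of a real acquisition, where a small fraction
#' (default 0.76%) of feature cells is unusable and imputed.
#'
#' @param cohort a \linkS4class{PupilCohort}
#' @param rate missing fraction in `[0, 1)`; defaults to the cohort
#'   config's `missingnessRate`
#' @param seed integer seed (defaults to cohort seed + 1)
#' @return the cohort with its `missingMask` slot populated
#' @export
injectMissingness <- function(cohort, rate = NULL, seed = NULL) {
  stopifnot(is(cohort, "PupilCohort"))
  cfg <- cohort@metadata$config
  if (is.null(rate)) rate <- cfg$missingnessRate
  if (is.null(rate)) stop("no rate given and none in cohort metadata")
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (is.null(seed)) seed <- (cohort@metadata$seed %||% 0L) + 1L
  tr <- data.table::as.data.table(cohort@traces)
  resp <- unique(tr[, c("subject_id", "eye", "condition", "target_index")])
  data.table::setorder(resp, condition, eye, subject_id, target_index)
  set.seed(seed)
  hit <- runif(nrow(resp)) < rate
  cohort@mask <- as.data.frame(resp[hit])
  cohort@metadata$missingnessRate <- rate
  cohort
}

`%||%` <- function(a, b) if (is.null(a)) b else a
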