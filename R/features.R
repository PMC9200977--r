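## Savitzky-Golay smoothing/differentiation and extraction of the 17 PLR
## kinetic parameters.

.sgCache <- new.env(parent = emptyenv())

## Full-length Savitzky-Golay operator as an nT x nT matrix (interior rows:
## central projection row; edge rows: the asymmetric rows of the projection
## matrix), so a whole cohort's traces can be filtered with one matrix
## product. Equivalent to signal::sgolayfilt applied per trace (asserted in
## the test suite).
.sgOperator <- function(nT, window, poly, m, dt) {
  key <- paste(nT, window, poly, m, signif(dt, 12), sep = "|")
  if (!is.null(.sgCache[[key]])) return(.sgCache[[key]])
  F <- signal::sgolay(p = poly, n = window, m = m)
  k <- (window - 1L) / 2L
  S <- matrix(0, nT, nT)
  for (i in seq_len(k)) S[i, 1:window] <- F[i, ]
  for (i in (k + 1L):(nT - k)) S[i, (i - k):(i + k)] <- F[k + 1L, ]
  for (i in seq_len(k)) S[nT - k + i, (nT - window + 1L):nT] <- F[k + 1L + i, ]
  S <- S * factorial(m) / dt^m
  .sgCache[[key]] <- S
  S
}

#' Extraction settings for the PLR feature extractor
#'
#' @param window Savitzky-Golay window (samples, odd) for the smoothed
#'   diameter and its derivatives
#' @param polyOrder local polynomial order
#' @param onsetWindow separate (smaller) SG window used only for the
#'   velocity trace feeding onset detection; a narrow window keeps the
#'   smoothing leak around the onset kink below one sample
#' @param onsetThresholdFrac onset trigger threshold as a fraction of the
#'   maximal contraction velocity
#' @param noiseFloorK multiple of the robust pre-onset velocity SD used
#'   both as a noise floor (below it no onset is reported) and as an
#'   adaptive lower bound on the trigger threshold
#' @param minMCV absolute noise floor for the maximal contraction velocity
#'   (mm/s); traces below it yield undefined features
#' @param contractionExtra seconds past stimulus offset included in the
#'   contraction window when locating the trough
#' @param maxMissingFrac traces with more than this fraction of missing
#'   samples are rejected (all features undefined)
#' @return settings list of class `plrSettings`
#' @export
plrSettings <- function(window = 7L, polyOrder = 2L, onsetWindow = 5L,
                        onsetThresholdFrac = 0.1, noiseFloorK = 3,
                        minMCV = 0.05, contractionExtra = 1,
                        maxMissingFrac = 0.5) {
  if (window %% 2 == 0 || window < polyOrder + 2)
    stop("window must be odd and >= polyOrder + 2")
  if (onsetWindow %% 2 == 0 || onsetWindow < polyOrder + 2)
    stop("onsetWindow must be odd and >= polyOrder + 2")
  structure(list(window = as.integer(window),
                 polyOrder = as.integer(polyOrder),
                 onsetWindow = as.integer(onsetWindow),
                 onsetThresholdFrac = onsetThresholdFrac,
                 noiseFloorK = noiseFloorK, minMCV = minMCV,
                 contractionExtra = contractionExtra,
                 maxMissingFrac = maxMissingFrac),
            class = "plrSettings")
}

.checkUniform <- function(t) {
  dt <- diff(t)
  length(t) >= 8 && all(abs(dt - dt[1]) < 1e-6) && dt[1] > 0
}

#' Smooth a pupil trace and differentiate it
#'
#' Local-polynomial (Savitzky-Golay) smoothing of the diameter trace with
#' analytic first and second derivatives of the local fit. Missing samples
#' are linearly interpolated before smoothing and re-flagged in the output.
#'
#' @param trace `data.frame` with columns `time_s` and `diameter_mm` on a
#'   uniform time grid (as produced by [simulateTrace()])
#' @param window,polyOrder SG window (odd samples) and polynomial order
#' @param maxMissingFrac reject the trace (error) when more than this
#'   fraction of samples is missing
#' @return `data.frame` (a kinematic series) with columns `time_s`,
#'   `diameter_mm` (smoothed), `velocity_mm_s`, `acceleration_mm_s2`,
#'   `missing` (logical: sample was interpolated)
#' @export
smoothDifferentiate <- function(trace, window = 7L, polyOrder = 2L,
                                maxMissingFrac = 0.5) {
  t <- trace$time_s
  d <- trace$diameter_mm
  if (!.checkUniform(t)) stop("trace must be on a uniform time grid")
  miss <- !is.finite(d)
  if (mean(miss) > maxMissingFrac)
    stop(sprintf("trace unusable: %.0f%% of samples missing",
                 100 * mean(miss)))
  if (any(miss))
    d <- approx(t[!miss], d[!miss], xout = t, rule = 2)$y
  dt <- t[2] - t[1]
  nT <- length(t)
  S0 <- .sgOperator(nT, window, polyOrder, 0L, dt)
  S1 <- .sgOperator(nT, window, polyOrder, 1L, dt)
  S2 <- .sgOperator(nT, window, polyOrder, 2L, dt)
  data.frame(time_s = t,
             diameter_mm = as.vector(S0 %*% d),
             velocity_mm_s = as.vector(S1 %*% d),
             acceleration_mm_s2 = as.vector(S2 %*% d),
             missing = miss)
}

#' Detect the contraction onset (pupil response latency)
#'
#' The onset trigger is the first time after stimulus onset at which the
#' (negative) contraction velocity stays beyond a threshold for at least 3
#' consecutive samples. The threshold is
#' `max(thresholdFrac * MCV, noiseFloorK * robust pre-onset velocity SD)`;
#' the reported latency is the linearly interpolated crossing of that
#' threshold, corrected for the noise-driven part of the threshold by
#' extrapolation along the secant to a higher crossing. Returns `NA` when
#' the maximal contraction velocity does not rise above the noise floor
#' (no contraction detected): undefined is a value, not an error.
#'
#' @param kin kinematic series from [smoothDifferentiate()]
#' @param stimulusOnset stimulus onset time (s); traces start at 0
#' @param thresholdFrac trigger threshold as a fraction of MCV
#' @param noiseFloorK noise-floor multiplier (robust SDs)
#' @param minMCV absolute MCV noise floor (mm/s)
#' @param searchEnd latest onset time considered (s)
#' @return latency from `stimulusOnset` (s), or `NA`
#' @export
detectOnset <- function(kin, stimulusOnset = 0, thresholdFrac = 0.1,
                        noiseFloorK = 3, minMCV = 0.05, searchEnd = Inf) {
  v <- kin$velocity_mm_s
  t <- kin$time_s
  se <- min(searchEnd, max(t))
  prl <- .cpp_detect_onset(t, v, v, se, thresholdFrac, noiseFloorK, minMCV)
  if (is.na(prl)) NA_real_ else prl - stimulusOnset
}

## internal: smooth one diameter matrix (time x traces) and extract the
## 17 parameters for every column
.extractMatrix <- function(tGrid, D, stimDur, settings) {
  nT <- length(tGrid)
  dt <- tGrid[2] - tGrid[1]
  miss <- !is.finite(D)
  missFrac <- colMeans(miss)
  bad <- missFrac > settings$maxMissingFrac
  if (any(miss)) {
    for (j in which(colSums(miss) > 0 & !bad)) {
      ok <- !miss[, j]
      D[, j] <- approx(tGrid[ok], D[ok, j], xout = tGrid, rule = 2)$y
    }
    D[, bad] <- 0
  }
  S0 <- .sgOperator(nT, settings$window, settings$polyOrder, 0L, dt)
  S1 <- .sgOperator(nT, settings$window, settings$polyOrder, 1L, dt)
  S2 <- .sgOperator(nT, settings$window, settings$polyOrder, 2L, dt)
  S1o <- .sgOperator(nT, settings$onsetWindow, settings$polyOrder, 1L, dt)
  feat <- .cpp_extract_many(tGrid, S0 %*% D, S1 %*% D, S2 %*% D, S1o %*% D,
                            D, stimDur, settings$onsetThresholdFrac,
                            settings$noiseFloorK, settings$minMCV,
                            settings$contractionExtra)
  feat[, bad] <- NA_real_
  rownames(feat) <- .PLR_PARAMS
  feat
}

#' Extract the 17 PLR parameters from a single trace
#'
#' Operational definitions: the baseline diameter D_b is the mean smoothed
#' diameter before the detected onset; the trough is the minimal smoothed
#' diameter within the contraction window (onset to stimulus offset + 1 s);
#' AC = D_b - trough (mm), PPC = 100 AC / D_b (%), PRL is the detected
#' onset (see [detectOnset()]), LMP the trough time; MCV/MCA/MCD are the
#' maximal contraction velocity, acceleration and deceleration between PRL
#' and LMP with latencies LMCV/LMCA/LMCD (all latencies from stimulus
#' onset); MRV/MRA/MRD and their latencies are defined symmetrically on the
#' post-trough redilation segment; PRP = 100 (D_end - trough)/AC clipped to
#' \[0, 100\]. Any parameter whose defining extremum does not exist is NA;
#' a rejected trace (no detectable contraction, or too many missing
#' samples) yields all-NA.
#'
#' @param trace `data.frame` with `time_s`, `diameter_mm`
#' @param settings a [plrSettings()] object
#' @param stimDuration stimulus duration (s); defaults to the trace's
#'   `condition` attribute, else 1 s
#' @return named numeric vector of length 17 (see [plrParameters()])
#' @examples
#' tr <- simulateTrace(plrShapeParams(baseline = 6, amplitude = 0.9))
#' extractParameters(tr)[c("AC", "PPC", "PRL")]
#' @export
extractParameters <- function(trace, settings = plrSettings(),
                              stimDuration = NULL) {
  if (is.null(stimDuration)) {
    cond <- attr(trace, "condition")
    stimDuration <- if (!is.null(cond)) stimulusSpec(cond)$stim_duration_s
                    else 1
  }
  t <- trace$time_s
  if (!.checkUniform(t)) stop("trace must be on a uniform time grid")
  D <- matrix(trace$diameter_mm, ncol = 1)
  feat <- .extractMatrix(t, D, stimDuration, settings)
  setNames(feat[, 1], .PLR_PARAMS)
}

#' Extract PLR features for a whole cohort
#'
#' Vectorised extraction of the 17 parameters for every
#' (subject, eye, condition, target) trace. Responses listed in the
#' cohort's missingness mask are emitted as all-NA (they will be imputed in
#' the feature tables); so are traces rejected for excessive sample
#' missingness or absent contraction.
#'
#' @param cohort a \linkS4class{PupilCohort}
#' @param settings a [plrSettings()] object
#' @return `data.frame` with columns `subject_id`, `eye`, `condition`,
#'   `target_index`, `masked` (flag from the missingness mask) and the 17
#'   parameter columns
#' @export
extractFeatures <- function(cohort, settings = plrSettings()) {
  stopifnot(is(cohort, "PupilCohort"))
  tr <- data.table::as.data.table(cohort@traces)
  data.table::setorder(tr, condition, eye, subject_id, target_index, time_s)
  out <- list()
  for (cond in unique(tr$condition)) {
    sub <- tr[tr$condition == cond]
    spec <- stimulusSpec(cond)
    tGrid <- sort(unique(sub$time_s))
    nT <- length(tGrid)
    if (nrow(sub) %% nT != 0)
      stop("ragged traces in condition ", cond)
    m <- nrow(sub) %/% nT
    key <- sub[seq(1, nrow(sub), by = nT),
               c("subject_id", "eye", "condition", "target_index")]
    D <- matrix(sub$diameter_mm, nrow = nT)
    feat <- .extractMatrix(tGrid, D, spec$stim_duration_s, settings)
    block <- cbind(as.data.frame(key), as.data.frame(t(feat)))
    out[[cond]] <- block
  }
  res <- data.table::rbindlist(out)
  ## apply the feature-level missingness mask
  res$masked <- FALSE
  if (nrow(cohort@mask)) {
    mk <- data.table::as.data.table(cohort@mask)
    mk$masked2 <- TRUE
    res <- merge(res, mk,
                 by = c("subject_id", "eye", "condition", "target_index"),
                 all.x = TRUE, sort = FALSE)
    hit <- !is.na(res$masked2)
    for (p in .PLR_PARAMS) data.table::set(res, which(hit), p, NA_real_)
    res$masked <- hit
    res$masked2 <- NULL
  }
  data.table::setorder(res, condition, eye, subject_id, target_index)
  as.data.frame(res)
}
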