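## Long-format delimited-text I/O and JSON run configuration.

#' Write pupil traces to long-format delimited text
#'
#' One row per sample with columns `subject_id`, `eye`, `condition`,
#' `target_index`, `time_s`, `diameter_mm`; missing diameters are written
#' as empty fields.
#'
#' @param cohort a \linkS4class{PupilCohort}
#' @param path output file (`.tsv`/`.csv`; delimiter inferred from the
#'   extension, tab otherwise)
#' @param subjectsPath optional path for the subject table
#' @return `path`, invisibly
#' @export
writeTraces <- function(cohort, path, subjectsPath = NULL) {
  stopifnot(is(cohort, "PupilCohort"))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(cohort@traces, path, sep = sep, na = "")
  if (!is.null(subjectsPath)) writeSubjects(cohort@subjects, subjectsPath)
  invisible(path)
}

#' @rdname writeTraces
#' @param subjects subject `data.frame`
#' @export
writeSubjects <- function(subjects, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(subjects, path, sep = sep, na = "")
  invisible(path)
}

#' Read pupil traces from long-format delimited text
#'
#' Parses the long trace format written by [writeTraces()]. Traces whose
#' time stamps are not a strictly increasing uniform grid are rejected
#' individually (with a warning naming the trace); the remaining traces
#' are kept. An empty file yields an empty cohort with a warning.
#'
#' @param path trace file
#' @param subjectsPath optional subject table (`subject_id`, `group`,
#'   `age_years`, `sex`); when absent, subjects are listed with unknown
#'   group
#' @return a \linkS4class{PupilCohort} (with empty ground-truth slot)
#' @export
readTraces <- function(path, subjectsPath = NULL) {
  tr <- data.table::fread(path, na.strings = c("", "NA"))
  need <- c("subject_id", "eye", "condition", "target_index", "time_s",
            "diameter_mm")
  if (nrow(tr) == 0L) {
    warning("empty trace file: ", path)
    tr <- data.table::as.data.table(
      setNames(list(character(), character(), character(), integer(),
                    numeric(), numeric()), need))
  }
  if (!all(need %in% names(tr)))
    stop("trace file must have columns: ", paste(need, collapse = ", "))
  tr <- tr[, need, with = FALSE]

  ## per-trace validation: strictly increasing uniform time grid
  key <- c("subject_id", "eye", "condition", "target_index")
  ok <- tr[, list(valid = {
    dt <- diff(time_s)
    length(time_s) >= 2 && all(dt > 0) && all(abs(dt - dt[1]) < 1e-6)
  }), by = key]
  bad <- ok[!ok$valid]
  if (nrow(bad)) {
    warning(nrow(bad), " trace(s) rejected (non-uniform time grid), e.g. ",
            paste(bad$subject_id[1], bad$eye[1], bad$condition[1],
                  bad$target_index[1]))
    tr <- merge(tr, ok, by = key, sort = FALSE)[valid == TRUE]
    tr$valid <- NULL
  }

  if (!is.null(subjectsPath)) {
    subj <- as.data.frame(data.table::fread(subjectsPath,
                                            na.strings = c("", "NA")))
  } else {
    ids <- sort(unique(tr$subject_id))
    subj <- data.frame(subject_id = ids, group = rep("FHneg", length(ids)),
                       age_years = rep(NA_real_, length(ids)),
                       sex = rep(NA_character_, length(ids)),
                       stringsAsFactors = FALSE)
  }
  cohort <- new("PupilCohort", traces = tr, subjects = subj,
                truth = data.frame(),
                mask = data.frame(subject_id = character(),
                                  eye = character(), condition = character(),
                                  target_index = integer()),
                metadata = list(source = path))
  validObject(cohort)
  cohort
}

#' Write / read the long feature table
#'
#' @param features feature `data.frame` from [extractFeatures()]
#' @param path `.tsv`/`.csv` path
#' @export
writeFeatures <- function(features, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  data.table::fwrite(features, path, sep = sep, na = "")
  invisible(path)
}

#' @rdname writeFeatures
#' @export
readFeatures <- function(path) {
  as.data.frame(data.table::fread(path, na.strings = c("", "NA")))
}

#' Full pipeline run configuration
#'
#' @param cohort a [cohortConfig()] (or list of its arguments)
#' @param settings a [plrSettings()] (or list of its arguments)
#' @param replicates bootstrap replicates B per model
#' @param rounds AdaBoost rounds per replicate
#' @param weightThreshold focal target selection cutoff
#' @param focalTop optional top-n focal selection rule (overrides the
#'   threshold; see [selectDiscriminativeTargets()])
#' @param preprocess `"replicate"` or `"global"` (see [bootstrapAUC()])
#' @param seed master seed for the bootstrap stage
#' @param outDir optional directory for JSON results
#' @return config list of class `runConfig`
#' @export
runConfig <- function(cohort = cohortConfig(), settings = plrSettings(),
                      replicates = 2000L, rounds = 50L,
                      weightThreshold = 0.47, focalTop = NULL,
                      preprocess = c("replicate", "global"), seed = 1L,
                      outDir = NULL) {
  if (!inherits(cohort, "cohortConfig"))
    cohort <- do.call(cohortConfig, as.list(cohort))
  if (!inherits(settings, "plrSettings"))
    settings <- do.call(plrSettings, as.list(settings))
  structure(list(cohort = cohort, settings = settings,
                 replicates = as.integer(replicates),
                 rounds = as.integer(rounds),
                 weightThreshold = weightThreshold, focalTop = focalTop,
                 preprocess = match.arg(preprocess),
                 seed = as.integer(seed), outDir = outDir),
            class = "runConfig")
}

#' Read a run configuration from JSON
#'
#' The JSON object may contain any subset of the [runConfig()] fields;
#' `cohort` and `settings` are nested objects of [cohortConfig()] /
#' [plrSettings()] arguments.
#'
#' @param path JSON file
#' @return a `runConfig`
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(raw$cohort)) args$cohort <- do.call(cohortConfig, raw$cohort)
  if (!is.null(raw$settings))
    args$settings <- do.call(plrSettings, raw$settings)
  for (f in c("replicates", "rounds", "weightThreshold", "focalTop",
              "preprocess", "seed", "outDir"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  do.call(runConfig, args)
}
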