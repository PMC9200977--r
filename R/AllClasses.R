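## Central S4 containers.

#' PupilCohort: a set of pupil-diameter traces plus subject metadata
#'
#' Container for one chromatic pupilloperimetry dataset: the long-format
#' trace table, the subject table, optional per-trace ground-truth shape
#' parameters (present for simulated cohorts), and a missingness mask at the
#' (subject, eye, condition, target) response level.
#'
#' @slot traces \code{data.table} with columns \code{subject_id}, \code{eye},
#'   \code{condition}, \code{target_index}, \code{time_s}, \code{diameter_mm};
#'   one row per sample, each trace on a uniform time grid starting at the
#'   stimulus onset (t = 0).
#' @slot subjects \code{data.frame} with columns \code{subject_id},
#'   \code{group} (\code{"FHpos"}/\code{"FHneg"}), \code{age_years},
#'   \code{sex}.
#' @slot truth \code{data.frame} of generating shape parameters per
#'   (subject, eye, condition, target); zero rows for recorded data.
#' @slot mask \code{data.frame} of responses flagged missing at the feature
#'   level (columns \code{subject_id}, \code{eye}, \code{condition},
#'   \code{target_index}).
#' @slot metadata \code{list}; simulation config, seed, retest counts.
#'
#' @seealso [simulateCohort()], [injectMissingness()], [extractFeatures()]
#' @export
setClass("PupilCohort",
  representation(
    traces = "data.frame",
    subjects = "data.frame",
    truth = "data.frame",
    mask = "data.frame",
    metadata = "list"
  )
)

setValidity("PupilCohort", function(object) {
  msg <- character()
  need <- c("subject_id", "eye", "condition", "target_index", "time_s",
            "diameter_mm")
  if (!all(need %in% names(object@traces)))
    msg <- c(msg, paste("traces must have columns:",
                        paste(need, collapse = ", ")))
  sneed <- c("subject_id", "group", "age_years")
  if (!all(sneed %in% names(object@subjects)))
    msg <- c(msg, paste("subjects must have columns:",
                        paste(sneed, collapse = ", ")))
  if (nrow(object@subjects) &&
      !all(object@subjects$group %in% c("FHpos", "FHneg")))
    msg <- c(msg, "subject group must be 'FHpos' or 'FHneg'")
  if (length(msg)) msg else TRUE
})

#' FeatureTable: subjects x visual-field targets for one PLR parameter
#'
#' A \linkS4class{SummarizedExperiment} whose single assay holds one PLR
#' parameter measured at every visual-field target (rows = targets, columns
#' = subjects) for one stimulus condition and one eye. \code{colData} carries
#' the binary family-history label and age. Dim-light tables have 54 feature
#' rows, bright-light tables 4.
#'
#' @slot parameter one of the 17 PLR parameter abbreviations (e.g.
#'   \code{"PRL"}).
#' @slot condition \code{"dim_red"}, \code{"dim_blue"}, \code{"bright_red"}
#'   or \code{"bright_blue"}.
#' @slot eye \code{"right"} or \code{"left"}.
#'
#' @seealso [buildFeatureTables()], [featureMatrix()], [bootstrapAUC()]
#' @export
setClass("FeatureTable",
  contains = "SummarizedExperiment",
  representation(
    parameter = "character",
    condition = "character",
    eye = "character"
  )
)

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (!nrow(object) %in% c(54L, 4L))
    msg <- c(msg, "a FeatureTable must have 54 (dim) or 4 (bright) features")
  cd <- colData(object)
  if (!all(c("label", "age") %in% names(cd)))
    msg <- c(msg, "colData must have 'label' and 'age'")
  else if (!all(cd$label %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1")
  if (length(object@parameter) != 1L || length(object@condition) != 1L ||
      length(object@eye) != 1L)
    msg <- c(msg, "parameter, condition and eye must be single strings")
  if (length(msg)) msg else TRUE
})

#' BoostedModel: a trained discrete AdaBoost stump ensemble
#'
#' @slot stumps \code{data.frame} with one row per boosting round kept:
#'   \code{feature} (1-based column index), \code{threshold},
#'   \code{polarity} (+1: predict positive above the threshold, -1 below)
#'   and the stage weight \code{alpha}.
#' @slot featureNames character vector naming the training columns.
#' @slot rounds number of rounds requested.
#'
#' @seealso [trainAdaBoost()], [predictScore()], [featureWeights()]
#' @export
setClass("BoostedModel",
  representation(
    stumps = "data.frame",
    featureNames = "character",
    rounds = "integer"
  )
)

setValidity("BoostedModel", function(object) {
  msg <- character()
  need <- c("feature", "threshold", "polarity", "alpha")
  if (!all(need %in% names(object@stumps)))
    msg <- c(msg, "stumps needs columns feature, threshold, polarity, alpha")
  else {
    if (nrow(object@stumps) > object@rounds)
      msg <- c(msg, "more stumps than rounds")
    if (nrow(object@stumps) &&
        (any(object@stumps$feature < 1) ||
         any(object@stumps$feature > length(object@featureNames))))
      msg <- c(msg, "stump feature index out of range")
  }
  if (length(msg)) msg else TRUE
})

#' BootstrapResult: stratified bootstrap out-of-bag evaluation of one model
#'
#' @slot parameter,condition,eye identity of the evaluated feature table.
#' @slot B number of bootstrap replicates requested.
#' @slot aucs out-of-bag AUC-ROC per non-degenerate replicate.
#' @slot weightMap per-target feature weights averaged over replicates,
#'   renormalised to sum to 1.
#' @slot meanOobSize mean number of distinct out-of-bag subjects.
#' @slot nSkipped replicates skipped because the out-of-bag set lacked a
#'   class.
#' @slot seed master seed used.
#'
#' @seealso [bootstrapAUC()], [weightMap()], [aucSummary()]
#' @export
setClass("BootstrapResult",
  representation(
    parameter = "character",
    condition = "character",
    eye = "character",
    B = "integer",
    aucs = "numeric",
    weightMap = "numeric",
    meanOobSize = "numeric",
    nSkipped = "integer",
    seed = "integer"
  )
)

setValidity("BootstrapResult", function(object) {
  msg <- character()
  if (length(object@aucs) + object@nSkipped != object@B)
    msg <- c(msg, "replicates + skipped must equal B")
  if (length(object@weightMap) &&
      abs(sum(object@weightMap) - 1) > 1e-8)
    msg <- c(msg, "weightMap must sum to 1")
  if (any(object@weightMap < 0))
    msg <- c(msg, "weightMap must be non-negative")
  if (length(msg)) msg else TRUE
})
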