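#' @rdname PupilCohort-class
#' @param object,x a \linkS4class{PupilCohort}, \linkS4class{FeatureTable},
#'   \linkS4class{BoostedModel} or \linkS4class{BootstrapResult}
#' @export
setGeneric("traces", function(x) standardGeneric("traces"))

#' @rdname PupilCohort-class
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' @rdname PupilCohort-class
#' @export
setGeneric("truthParams", function(x) standardGeneric("truthParams"))

#' @rdname PupilCohort-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname FeatureTable-class
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname FeatureTable-class
#' @export
setGeneric("fhLabels", function(x) standardGeneric("fhLabels"))

#' @rdname FeatureTable-class
#' @export
setGeneric("subjectAges", function(x) standardGeneric("subjectAges"))

#' @rdname BoostedModel-class
#' @export
setGeneric("stumps", function(x) standardGeneric("stumps"))

#' Per-feature weights of a boosted model or bootstrap result
#'
#' For a \linkS4class{BoostedModel}: the normalised sum of |alpha| over the
#' stumps using each feature (non-negative, sums to 1). For a
#' \linkS4class{BootstrapResult}: the replicate-averaged weight map.
#'
#' @param x a \linkS4class{BoostedModel} or \linkS4class{BootstrapResult}
#' @return named numeric vector over features (visual-field targets)
#' @export
setGeneric("featureWeights", function(x) standardGeneric("featureWeights"))

#' @rdname BootstrapResult-class
#' @export
setGeneric("weightMap", function(x) standardGeneric("weightMap"))

#' @rdname BootstrapResult-class
#' @export
setGeneric("aucSummary", function(x) standardGeneric("aucSummary"))

#' @rdname BootstrapResult-class
#' @export
setGeneric("aucReplicates", function(x) standardGeneric("aucReplicates"))
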