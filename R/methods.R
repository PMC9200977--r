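## Accessors and show methods.

#' @rdname PupilCohort-class
#' @export
setMethod("traces", "PupilCohort", function(x) x@traces)

#' @rdname PupilCohort-class
#' @export
setMethod("subjects", "PupilCohort", function(x) x@subjects)

#' @rdname PupilCohort-class
#' @export
setMethod("truthParams", "PupilCohort", function(x) x@truth)

#' @rdname PupilCohort-class
#' @export
setMethod("missingMask", "PupilCohort", function(x) x@mask)

setMethod("show", "PupilCohort", function(object) {
  tr <- object@traces
  nTrace <- if (nrow(tr))
    nrow(unique(tr[, c("subject_id", "eye", "condition", "target_index")]))
  else 0L
  cat("PupilCohort:", nrow(object@subjects), "subjects (",
      sum(object@subjects$group == "FHpos"), "FH+ /",
      sum(object@subjects$group == "FHneg"), "FH- ),",
      nTrace, "traces\n")
  cat("  conditions:", paste(unique(tr$condition), collapse = ", "), "\n")
  cat("  eyes:      ", paste(unique(tr$eye), collapse = ", "), "\n")
  cat("  masked responses:", nrow(object@mask), "\n")
})

#' @rdname FeatureTable-class
#' @param x a \code{FeatureTable}
#' @return \code{featureMatrix}: subjects x features numeric matrix (columns
#'   in visual-field index order); \code{fhLabels}: integer 0/1 vector
#'   (1 = FH+); \code{subjectAges}: numeric vector of ages in years.
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) t(assay(x)))

#' @rdname FeatureTable-class
#' @export
setMethod("fhLabels", "FeatureTable", function(x) {
  setNames(as.integer(colData(x)$label), colnames(x))
})

#' @rdname FeatureTable-class
#' @export
setMethod("subjectAges", "FeatureTable", function(x) {
  setNames(as.numeric(colData(x)$age), colnames(x))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable %s | %s | %s eye: %d subjects x %d targets (%d FH+), %d missing cells\n",
              object@parameter, object@condition, object@eye,
              ncol(object), nrow(object), sum(colData(object)$label == 1L),
              sum(is.na(assay(object)))))
})

#' @rdname BoostedModel-class
#' @param x a \code{BoostedModel}
#' @export
setMethod("stumps", "BoostedModel", function(x) x@stumps)

#' @rdname featureWeights
#' @export
setMethod("featureWeights", "BoostedModel", function(x) {
  w <- numeric(length(x@featureNames))
  names(w) <- x@featureNames
  if (nrow(x@stumps)) {
    agg <- tapply(abs(x@stumps$alpha), x@stumps$feature, sum)
    w[as.integer(names(agg))] <- agg
    tot <- sum(w)
    if (tot > 0) w <- w / tot
  }
  w
})

setMethod("show", "BoostedModel", function(object) {
  cat(sprintf("BoostedModel: %d stumps (of %d rounds) over %d features\n",
              nrow(object@stumps), object@rounds,
              length(object@featureNames)))
  if (nrow(object@stumps)) {
    top <- sort(featureWeights(object), decreasing = TRUE)
    top <- top[top > 0]
    cat("  top weights:",
        paste(sprintf("%s=%.3f", names(head(top, 3)), head(top, 3)),
              collapse = ", "), "\n")
  }
})

#' @rdname BootstrapResult-class
#' @param x a \code{BootstrapResult}
#' @export
setMethod("weightMap", "BootstrapResult", function(x) x@weightMap)

#' @rdname featureWeights
#' @export
setMethod("featureWeights", "BootstrapResult", function(x) x@weightMap)

#' @rdname BootstrapResult-class
#' @return \code{aucSummary}: named list with \code{mean}, \code{sd},
#'   \code{ci95} (percentile 2.5/97.5), \code{n} replicates used;
#'   \code{aucReplicates}: the per-replicate out-of-bag AUC vector.
#' @export
setMethod("aucSummary", "BootstrapResult", function(x) {
  list(mean = mean(x@aucs), sd = sd(x@aucs),
       ci95 = unname(quantile(x@aucs, c(0.025, 0.975))),
       n = length(x@aucs))
})

#' @rdname BootstrapResult-class
#' @export
setMethod("aucReplicates", "BootstrapResult", function(x) x@aucs)

setMethod("show", "BootstrapResult", function(object) {
  s <- aucSummary(object)
  cat(sprintf("BootstrapResult %s | %s | %s eye (B = %d, %d skipped)\n",
              object@parameter, object@condition, object@eye, object@B,
              object@nSkipped))
  cat(sprintf("  AUC-ROC %.3f +/- %.3f, 95%% CI [%.3f, %.3f], mean OOB size %.1f\n",
              s$mean, s$sd, s$ci95[1], s$ci95[2], object@meanOobSize))
})
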