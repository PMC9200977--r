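## Stratified bootstrap out-of-bag evaluation: AUC-ROC confidence
## intervals and averaged per-target weight maps.

#' One stratified bootstrap split
#'
#' Within each class, draws class-size samples with replacement; the
#' out-of-bag set is every subject never drawn. A replicate is degenerate
#' when the out-of-bag set lacks one of the classes.
#'
#' @param labels binary labels (0/1), both classes present
#' @param seed optional integer seed
#' @return list with `inBag` (indices, length = n, with repeats), `outOfBag`
#'   (distinct indices never drawn) and `degenerate` (logical)
#' @export
stratifiedBootstrapSplit <- function(labels, seed = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("single-class input: both classes must be present")
  if (!is.null(seed)) set.seed(seed)
  inBag <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- which(labels == cls)
    inBag <- c(inBag, sample(idx, length(idx), replace = TRUE))
  }
  oob <- setdiff(seq_along(labels), unique(inBag))
  degenerate <- length(unique(labels[oob])) < 2L
  list(inBag = inBag, outOfBag = oob, degenerate = degenerate)
}

#' Stratified bootstrap out-of-bag AUC-ROC for one feature table
#'
#' For each of `B` replicates: draw a stratified bootstrap sample, fit the
#' preprocessing (mean imputation, then min-max scaling to \[0, 1\]) on the
#' in-bag rows, train an AdaBoost stump ensemble on them, score the
#' out-of-bag subjects, and record the out-of-bag AUC-ROC and the model's
#' per-target feature weights. Degenerate replicates (out-of-bag set
#' lacking a class) are skipped and counted. Replicate seeds are drawn up
#' front from the master seed (`sample.int(2^31 - 1, B)`), so results are
#' fully reproducible and independent of evaluation order.
#'
#' @param table a \linkS4class{FeatureTable}
#' @param B number of bootstrap replicates (>= 2); the reference protocol
#'   uses 2000
#' @param rounds AdaBoost rounds per replicate
#' @param seed master seed
#' @param preprocess `"replicate"` (impute/scale fitted inside each
#'   replicate on the in-bag rows; leakage-safe default) or `"global"`
#'   (fitted once on the full table before resampling)
#' @return a \linkS4class{BootstrapResult}
#' @export
bootstrapAUC <- function(table, B = 2000L, rounds = 50L, seed = 1L,
                         preprocess = c("replicate", "global")) {
  stopifnot(is(table, "FeatureTable"))
  preprocess <- match.arg(preprocess)
  B <- as.integer(B)
  if (B < 2L) stop("B must be >= 2")
  X <- featureMatrix(table)
  y <- fhLabels(table)
  if (length(unique(y)) < 2L) stop("both classes required")

  if (preprocess == "global") {
    pp <- .preprocessFold(X, X)
    X <- pp$train
  }

  set.seed(as.integer(seed))
  repSeeds <- sample.int(.Machine$integer.max, B)

  aucs <- numeric(B)
  oobSizes <- numeric(B)
  W <- matrix(0, B, ncol(X))
  keep <- logical(B)

  for (b in seq_len(B)) {
    sp <- stratifiedBootstrapSplit(y, seed = repSeeds[b])
    if (sp$degenerate) next
    if (preprocess == "replicate") {
      pp <- .preprocessFold(X[sp$inBag, , drop = FALSE],
                            X[sp$outOfBag, , drop = FALSE])
      xtr <- pp$train; xte <- pp$test
    } else {
      xtr <- X[sp$inBag, , drop = FALSE]
      xte <- X[sp$outOfBag, , drop = FALSE]
    }
    model <- trainAdaBoost(xtr, y[sp$inBag], rounds = rounds)
    sc <- predictScore(model, xte)
    aucs[b] <- aucROC(sc, y[sp$outOfBag])
    W[b, ] <- featureWeights(model)
    oobSizes[b] <- length(sp$outOfBag)
    keep[b] <- TRUE
  }

  if (!any(keep)) stop("all replicates degenerate")
  wm <- aggregateWeightMap(W[keep, , drop = FALSE])
  names(wm) <- colnames(X)
  res <- new("BootstrapResult",
             parameter = table@parameter, condition = table@condition,
             eye = table@eye, B = B, aucs = aucs[keep], weightMap = wm,
             meanOobSize = mean(oobSizes[keep]),
             nSkipped = as.integer(sum(!keep)), seed = as.integer(seed))
  validObject(res)
  res
}

#' Average per-replicate weight maps
#'
#' Arithmetic mean across replicates, renormalised to sum to 1.
#'
#' @param weights matrix (replicates x targets) or list of weight vectors
#' @return numeric weight map summing to 1
#' @export
aggregateWeightMap <- function(weights) {
  if (is.list(weights)) weights <- do.call(rbind, weights)
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1)
  if (nrow(weights) < 1L) stop("need at least one replicate")
  m <- colMeans(weights)
  tot <- sum(m)
  if (tot > 0) m <- m / tot
  m
}
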