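## Discrete AdaBoost with decision stumps, ensemble scoring, and AUC-ROC.

#' Train a discrete AdaBoost stump ensemble
#'
#' Depth-1 threshold stumps boosted under the exponential loss: each round
#' selects the (feature, threshold, polarity) triple minimising the
#' weighted 0-1 error, with thresholds at midpoints between consecutive
#' distinct sorted values. Training stops early when the best weighted
#' error reaches 0 or 0.5. Entirely deterministic: ties are broken by
#' lowest feature index, then lowest threshold.
#'
#' @param x numeric matrix (subjects x features), no missing values
#' @param y binary labels (0/1 or logical), both classes present
#' @param rounds maximal number of boosting rounds T
#' @return a \linkS4class{BoostedModel}
#' @examples
#' x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
#' m <- trainAdaBoost(x, c(0, 0, 0, 1, 1, 1), rounds = 5)
#' sign(predictScore(m, x))
#' @export
trainAdaBoost <- function(x, y, rounds = 50L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(y) != nrow(x)) stop("length(y) must match nrow(x)")
  if (length(unique(y)) < 2L)
    stop("single-class training set: both classes must be present")
  if (anyNA(x)) stop("x must not contain missing values (impute first)")
  fit <- .cpp_adaboost_train(x, y, as.integer(rounds))
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("F", seq_len(ncol(x)))
  model <- new("BoostedModel",
               stumps = data.frame(feature = as.integer(fit$feature),
                                   threshold = as.numeric(fit$threshold),
                                   polarity = as.numeric(fit$polarity),
                                   alpha = as.numeric(fit$alpha)),
               featureNames = nm, rounds = as.integer(rounds))
  validObject(model)
  model
}

#' Score samples with a boosted model
#'
#' Signed ensemble margin `sum_t alpha_t h_t(x)`; monotone in the
#' predicted probability of the positive (FH+) class. Columns must align
#' with the training matrix (matched by name when both are named).
#'
#' @param model a \linkS4class{BoostedModel}
#' @param x numeric matrix with the training columns
#' @return numeric score per row
#' @export
predictScore <- function(model, x) {
  x <- as.matrix(x)
  nm <- colnames(x)
  if (!is.null(nm) && !identical(nm, model@featureNames)) {
    if (!all(model@featureNames %in% nm))
      stop("x is missing training feature columns")
    x <- x[, model@featureNames, drop = FALSE]
  } else if (ncol(x) != length(model@featureNames)) {
    stop("column mismatch: model was trained on ",
         length(model@featureNames), " features, x has ", ncol(x))
  }
  if (nrow(model@stumps) == 0L) return(numeric(nrow(x)))
  as.numeric(.cpp_adaboost_score(x, model@stumps$feature,
                                 model@stumps$threshold,
                                 model@stumps$polarity,
                                 model@stumps$alpha))
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly drawn positive outscores a randomly
#' drawn negative, with ties counted 1/2 — computed from average ranks.
#'
#' @param scores numeric scores (higher = more positive)
#' @param labels binary labels (0/1 or logical)
#' @return AUC in \[0, 1\]; `NA` (with a warning) if a class is absent
#' @examples
#' aucROC(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
#' @export
aucROC <- function(scores, labels) {
  labels <- as.integer(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels must not be NA")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
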