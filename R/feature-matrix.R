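## Assembly of per-(parameter, condition, eye) feature tables, mean
## imputation and min-max scaling.

#' Build one FeatureTable per (parameter, condition, eye)
#'
#' Splits the long feature data frame into subjects x targets matrices:
#' one per combination of the 17 PLR parameters, the stimulus conditions
#' present, and the two eyes — 136 tables for the full four-condition
#' protocol. Subjects lacking either eye are excluded with a warning (only
#' subjects with both eyes eligible enter the analysis). Tables are raw:
#' imputation and scaling are applied later (inside each bootstrap
#' replicate by default; see [bootstrapAUC()]).
#'
#' @param features long feature table from [extractFeatures()]
#' @param subjects subject table (`subject_id`, `group`, `age_years`); e.g.
#'   `subjects(cohort)`
#' @return named list of \linkS4class{FeatureTable} objects, keyed
#'   `"condition|eye|parameter"`, in canonical condition/eye/parameter
#'   order
#' @export
buildFeatureTables <- function(features, subjects) {
  ft <- data.table::as.data.table(features)
  eyesSeen <- unique(ft$eye)
  if (length(eyesSeen) > 1) {
    byEye <- ft[, list(nEyes = data.table::uniqueN(eye)),
                by = "subject_id"]
    incomplete <- byEye$subject_id[byEye$nEyes < length(eyesSeen)]
    if (length(incomplete)) {
      warning(length(incomplete),
              " subject(s) missing an eye excluded: ",
              paste(head(incomplete, 5), collapse = ", "))
      ft <- ft[!ft$subject_id %in% incomplete]
    }
  }
  subjects <- subjects[subjects$subject_id %in% unique(ft$subject_id), ]
  subjects <- subjects[order(subjects$subject_id), ]
  ids <- subjects$subject_id
  labels <- as.integer(subjects$group == "FHpos")
  ages <- subjects$age_years

  out <- list()
  conds <- intersect(.CONDITIONS, unique(ft$condition))
  for (cond in conds) {
    nTarg <- stimulusSpec(cond)$n_targets
    targets <- sort(unique(ft$target_index[ft$condition == cond]))
    for (eyeSide in intersect(.EYES, unique(ft$eye))) {
      keepRow <- which(ft$condition == cond & ft$eye == eyeSide)
      sub <- ft[keepRow]
      for (param in .PLR_PARAMS) {
        M <- matrix(NA_real_, length(targets), length(ids),
                    dimnames = list(paste0("T", targets), ids))
        M[cbind(match(sub$target_index, targets),
                match(sub$subject_id, ids))] <- sub[[param]]
        se <- SummarizedExperiment(
          assays = list(features = M),
          rowData = DataFrame(target_index = targets),
          colData = DataFrame(label = labels, age = ages, row.names = ids))
        tab <- new("FeatureTable", se, parameter = param,
                   condition = cond, eye = eyeSide)
        validObject(tab)
        out[[paste(cond, eyeSide, param, sep = "|")]] <- tab
      }
      if (length(targets) != nTarg)
        warning(sprintf("%s/%s: %d targets present, %d expected",
                        cond, eyeSide, length(targets), nTarg))
    }
  }
  out
}

#' Mean imputation fitted on training rows
#'
#' Replaces missing cells by the per-column training mean; test columns are
#' imputed with the training means (never their own). A training column
#' with no observed value is dropped from both matrices with a warning.
#'
#' @param train,test numeric matrices (subjects x features); `test` may be
#'   `NULL`
#' @return list with `train`, `test`, `means`, and `nImputed` (cells
#'   imputed across both matrices)
#' @export
imputeMean <- function(train, test = NULL) {
  means <- colMeans(train, na.rm = TRUE)
  empty <- !is.finite(means)
  if (any(empty)) {
    warning(sum(empty), " all-missing column(s) dropped: ",
            paste(colnames(train)[empty], collapse = ", "))
    train <- train[, !empty, drop = FALSE]
    test <- if (!is.null(test)) test[, !empty, drop = FALSE]
    means <- means[!empty]
  }
  nImp <- 0L
  fill <- function(M) {
    idx <- which(is.na(M), arr.ind = TRUE)
    nImp <<- nImp + nrow(idx)
    if (nrow(idx)) M[idx] <- means[idx[, 2]]
    M
  }
  train <- fill(train)
  if (!is.null(test)) test <- fill(test)
  list(train = train, test = test, means = means, nImputed = nImp)
}

#' Min-max scaling to \[0, 1\] fitted on training rows
#'
#' Per-column `(x - min) / (max - min)` using the training minimum and
#' maximum; test values outside the training range are clipped to \[0, 1\].
#' A constant training column maps to 0.5 everywhere (any constant is
#' equally uninformative).
#'
#' @param train,test numeric matrices without missing values (impute
#'   first); `test` may be `NULL`
#' @return list with `train`, `test`, `mins`, `maxs`
#' @export
minmaxScale <- function(train, test = NULL) {
  mins <- apply(train, 2, min)
  maxs <- apply(train, 2, max)
  rng <- maxs - mins
  const <- rng <= 0
  scale1 <- function(M) {
    M <- sweep(M, 2, mins, "-")
    M <- sweep(M, 2, ifelse(const, 1, rng), "/")
    M[, const] <- 0.5
    M[M < 0] <- 0
    M[M > 1] <- 1
    M
  }
  train <- scale1(train)
  if (!is.null(test)) test <- scale1(test)
  list(train = train, test = test, mins = mins, maxs = maxs)
}

## internal: impute + scale with training-fold fitting, preserving column
## alignment (an all-missing in-bag column becomes the constant 0.5 rather
## than being dropped, so the trained model's feature indices stay valid)
.preprocessFold <- function(train, test) {
  means <- colMeans(train, na.rm = TRUE)
  means[!is.finite(means)] <- 0.5
  idx <- which(is.na(train), arr.ind = TRUE)
  if (nrow(idx)) train[idx] <- means[idx[, 2]]
  idx <- which(is.na(test), arr.ind = TRUE)
  if (nrow(idx)) test[idx] <- means[idx[, 2]]
  sc <- minmaxScale(train, test)
  list(train = sc$train, test = sc$test)
}
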