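## Focal analysis: select high-weight targets and compare group latency,
## unadjusted and age-adjusted, with Bonferroni correction.

#' Select discriminative targets from a weight map
#'
#' Targets whose averaged model weight strictly exceeds `threshold`,
#' sorted by descending weight. An empty selection is allowed. With
#' `top = n`, the n highest-weight targets are returned instead; the
#' absolute weight scale depends on the ensemble size and the number of
#' informative targets, so a rank-based selection is often the more
#' portable rule (see the package vignette).
#'
#' @param map weight map (from [weightMap()]), named by target
#' @param threshold weight cutoff (the reference analysis used 0.47)
#' @param top optional number of top targets (overrides `threshold`)
#' @return integer target indices, descending weight order
#' @export
selectDiscriminativeTargets <- function(map, threshold = 0.47, top = NULL) {
  idx <- seq_along(map)
  nm <- names(map)
  targ <- if (!is.null(nm)) as.integer(sub("^T", "", nm)) else idx
  ord <- order(map, decreasing = TRUE)
  if (!is.null(top)) return(targ[ord[seq_len(min(top, length(map)))]])
  sel <- ord[map[ord] > threshold]
  targ[sel]
}

#' Two-sample group comparison (pooled-variance t-test)
#'
#' Two-sided two-sample t-test with pooled variance (Welch by
#' `varEqual = FALSE`), plus per-group means, standard errors and 95%
#' t confidence intervals.
#'
#' @param values numeric outcome per subject (e.g. mean PRL over selected
#'   targets); NA values are dropped pairwise with their labels
#' @param labels binary group labels (1 = FH+, 0 = FH-)
#' @param varEqual pool the variances (classical t-test) if `TRUE`
#' @return list with `groups` (data.frame: group, n, mean, se, ci_lo,
#'   ci_hi), `diff` (FH+ minus FH-), `t`, `df`, `p`
#' @examples
#' compareGroups(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0))$p  # ~0.021
#' @export
compareGroups <- function(values, labels, varEqual = TRUE) {
  labels <- as.integer(labels)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 < 2L || n0 < 2L)
    stop("each group needs >= 2 subjects with data")
  g <- function(cls) {
    v <- values[labels == cls]
    m <- mean(v); se <- sd(v) / sqrt(length(v))
    ci <- m + c(-1, 1) * qt(0.975, length(v) - 1) * se
    data.frame(group = if (cls == 1L) "FHpos" else "FHneg",
               n = length(v), mean = m, se = se,
               ci_lo = ci[1], ci_hi = ci[2])
  }
  groups <- rbind(g(0L), g(1L))
  if (var(values[labels == 1L]) + var(values[labels == 0L]) == 0) {
    d <- mean(values[labels == 1L]) - mean(values[labels == 0L])
    ## identical constant groups: no evidence against equality
    return(list(groups = groups, diff = d, t = if (d == 0) 0 else Inf,
                df = n1 + n0 - 2, p = if (d == 0) 1 else 0))
  }
  tt <- t.test(values[labels == 1L], values[labels == 0L],
               var.equal = varEqual)
  list(groups = groups,
       diff = unname(diff(rev(tt$estimate))),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Age-adjusted group comparison (general linear model)
#'
#' Fits `value ~ group + age` and reports each group's adjusted mean
#' evaluated at the overall mean age, with standard errors and 95% CIs
#' from the model covariance, and the group-effect p-value.
#'
#' @param values numeric outcome per subject
#' @param labels binary group labels (1 = FH+)
#' @param ages ages in years
#' @return list with `groups` (data.frame as in [compareGroups()]),
#'   `diff`, `p` (group coefficient), `fit` (the `lm` object)
#' @export
ageAdjustedComparison <- function(values, labels, ages) {
  labels <- as.integer(labels)
  ok <- is.finite(values) & !is.na(labels) & is.finite(ages)
  values <- values[ok]; labels <- labels[ok]; ages <- ages[ok]
  if (length(unique(labels)) < 2L) stop("both groups required")
  if (length(values) < 4L) stop("too few subjects")
  grp <- factor(labels, levels = c(0L, 1L))
  fit <- lm(values ~ grp + ages)
  if (any(is.na(coef(fit))))
    stop("degenerate design: group and age are collinear")
  sm <- summary(fit)
  abar <- mean(ages)
  V <- vcov(fit)
  dfree <- fit$df.residual
  adj <- function(cls) {
    xv <- c(1, as.numeric(cls == 1L), abar)
    m <- sum(xv * coef(fit))
    se <- sqrt(drop(t(xv) %*% V %*% xv))
    ci <- m + c(-1, 1) * qt(0.975, dfree) * se
    data.frame(group = if (cls == 1L) "FHpos" else "FHneg",
               n = sum(labels == cls), mean = m, se = se,
               ci_lo = ci[1], ci_hi = ci[2])
  }
  list(groups = rbind(adj(0L), adj(1L)),
       diff = unname(coef(fit)["grp1"]),
       p = sm$coefficients["grp1", "Pr(>|t|)"],
       fit = fit)
}

#' Bonferroni correction
#'
#' @param p raw p-values
#' @param m number of comparisons (defaults to `length(p)`)
#' @return corrected p-values `min(1, p * m)`
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  pmin(1, p * m)
}

#' Focal analysis of latency at the most discriminative targets
#'
#' End-to-end focal comparison for one eye: select targets from the
#' bootstrap-averaged weight map, average the (raw, pre-scaling) parameter
#' values over those targets per subject, and compare groups with the
#' pooled t-test and the age-adjusted linear model; p-values are
#' Bonferroni-corrected for the number of selected targets.
#'
#' @param table the \linkS4class{FeatureTable} the weight map refers to
#'   (raw values, e.g. dim-blue PRL of one eye)
#' @param result the matching \linkS4class{BootstrapResult}
#' @param threshold,top target selection rule (see
#'   [selectDiscriminativeTargets()])
#' @return list with `targets`, `m` (Bonferroni multiplier), and a
#'   `comparison` data.frame mirroring a two-model (unadjusted / adjusted)
#'   group table: per model and group the mean, SE, 95% CI, and the raw,
#'   corrected p-values plus a significance flag at corrected 0.05.
#'   `NULL` (with a message) when no target exceeds the threshold.
#' @export
focalAnalysis <- function(table, result, threshold = 0.47, top = NULL) {
  stopifnot(is(table, "FeatureTable"), is(result, "BootstrapResult"))
  if (table@parameter != result@parameter ||
      table@condition != result@condition || table@eye != result@eye)
    stop("table and result refer to different models")
  sel <- selectDiscriminativeTargets(weightMap(result), threshold, top)
  if (!length(sel)) {
    message("no target exceeds the weight threshold; nothing to compare")
    return(NULL)
  }
  X <- featureMatrix(table)
  cols <- match(paste0("T", sel), colnames(X))
  vals <- rowMeans(X[, cols, drop = FALSE], na.rm = TRUE)
  y <- fhLabels(table)
  ages <- subjectAges(table)
  m <- length(sel)

  un <- compareGroups(vals, y)
  ad <- ageAdjustedComparison(vals, y, ages)
  row <- function(modelName, cg) {
    cbind(model = modelName, cg$groups,
          p = cg$p, p_bonferroni = bonferroni(cg$p, m),
          significant = bonferroni(cg$p, m) < 0.05)
  }
  list(targets = sel, m = m,
       comparison = rbind(row("unadjusted", un), row("age_adjusted", ad)))
}
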