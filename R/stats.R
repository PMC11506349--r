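# Group statistics: mean/max/min summaries, two-group Student's t-tests
# and ROC/AUC for the three pairwise grade comparisons.

#' Summary statistics of a measurement vector
#' @param values Numeric vector with at least one finite value.
#' @return List with `mean`, `max`, `min`.
#' @export
summarizeValues <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L)
    stop("no finite values to summarize", call. = FALSE)
  list(mean = mean(values), max = max(values), min = min(values))
}

#' Two-group Student's t-test
#'
#' Pooled-variance two-sided Student's t-test (Welch correction via
#' `equalVariance = FALSE`).  Two groups with zero variance and equal
#' means return `t = 0, p = 1` by convention.  Significance is reported
#' at alpha = 0.05.
#'
#' @param groupA,groupB Numeric vectors, each of length >= 2.
#' @param equalVariance Pool the variances (classical Student's test).
#' @return List of class `TTestResult`: `statistic`, `df`, `p.value`,
#'   `means`, `alpha`, `significant`.
#' @export
tTestGroups <- function(groupA, groupB, equalVariance = TRUE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB)) {
      res <- list(statistic = 0, df = length(groupA) + length(groupB) - 2,
                  p.value = 1, means = c(mean(groupA), mean(groupB)),
                  alpha = 0.05, significant = FALSE)
      class(res) <- "TTestResult"
      return(res)
    }
  }
  ht <- stats::t.test(groupA, groupB, var.equal = equalVariance,
                      alternative = "two.sided")
  res <- list(statistic = unname(ht$statistic), df = unname(ht$parameter),
              p.value = ht$p.value,
              means = c(mean(groupA), mean(groupB)),
              alpha = 0.05, significant = ht$p.value < 0.05)
  class(res) <- "TTestResult"
  res
}

#' @export
print.TTestResult <- function(x, ...) {
  cat(sprintf("Student's t-test: t = %.4f, df = %.2f, p = %.4g (%s at alpha 0.05)\n",
              x$statistic, x$df, x$p.value,
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' ROC curve and AUC of a score against binary labels
#'
#' The curve sweeps the unique score values as thresholds (predicting
#' positive for scores at or above each threshold); the AUC is computed
#' through the Mann-Whitney U identity, with ties contributing 1/2, and
#' equals the trapezoidal integral of the curve.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Vector of class labels.
#' @param positiveLabel The label treated as positive.
#' @return List of class `RocResult`: `fpr`, `tpr`, `thresholds`, `auc`,
#'   `positive`.
#' @export
rocCurve <- function(scores, labels, positiveLabel) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positiveLabel
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L)
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  # Mann-Whitney identity; midranks give ties 1/2 credit
  r <- rank(scores)
  auc <- (sum(r[pos]) - nP * (nP + 1) / 2) / (nP * nN)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores[pos] >= t) / nP, numeric(1L)))
  fpr <- c(0, vapply(thr, function(t) sum(scores[!pos] >= t) / nN, numeric(1L)))
  res <- list(fpr = fpr, tpr = tpr, thresholds = c(Inf, thr), auc = auc,
              positive = positiveLabel)
  class(res) <- "RocResult"
  res
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (positive class '%s', %d thresholds)\n",
              x$auc, x$positive, length(x$thresholds)))
  invisible(x)
}

# malignancy order used to orient the positive class of each pair
.malignancyRank <- c(normal = 0, well = 1, poorly = 2)

#' Pairwise grade comparisons of one metric
#'
#' For every pair of grades present in the measurement table, computes a
#' Student's t-test and a ROC analysis of the chosen metric.  The ROC
#' positive class is the higher-malignancy grade of each pair (tumor over
#' normal, poorly over well differentiated); the summary additionally
#' reports the orientation-free `max(auc, 1 - auc)`.  No multiple-testing
#' correction is applied across the three pairs.
#'
#' @param table Measurement data.frame (see [validateMeasurements()]).
#' @param metric Metric name to compare (`metric_name` column value).
#' @param pooledTumor Also compare normal against the pooled tumor grades.
#' @return List of class `GradeComparisonReport`: one entry per pair with
#'   `tTest`, `roc`, `n`, plus a `summary` data.frame.
#' @export
gradeComparisonReport <- function(table, metric, pooledTumor = FALSE) {
  validateMeasurements(table)
  tab <- table[table$metric_name == metric & is.finite(table$value), ,
               drop = FALSE]
  grades <- intersect(.gradeLevels, unique(tab$grade_label))
  pairs <- list(c("normal", "poorly"), c("normal", "well"),
                c("poorly", "well"))
  out <- list()
  rows <- list()
  for (p in pairs) {
    nm <- paste(p, collapse = "_vs_")
    a <- tab$value[tab$grade_label == p[1L]]
    b <- tab$value[tab$grade_label == p[2L]]
    if (length(a) < 2L || length(b) < 2L) {
      warning(sprintf("pair %s skipped: grade missing or too few observations", nm),
              call. = FALSE)
      next
    }
    posLab <- p[which.max(.malignancyRank[p])]
    scores <- c(a, b)
    labs <- rep(p, c(length(a), length(b)))
    roc <- rocCurve(scores, labs, posLab)
    tt <- tTestGroups(a, b)
    out[[nm]] <- list(tTest = tt, roc = roc,
                      n = c(length(a), length(b)))
    rows[[nm]] <- data.frame(pair = nm, metric = metric,
                             positive = posLab,
                             n_a = length(a), n_b = length(b),
                             t = tt$statistic, p_value = tt$p.value,
                             auc = roc$auc,
                             auc_oriented = max(roc$auc, 1 - roc$auc))
  }
  if (pooledTumor && all(c("poorly", "well") %in% grades) &&
      "normal" %in% grades) {
    a <- tab$value[tab$grade_label == "normal"]
    b <- tab$value[tab$grade_label %in% c("poorly", "well")]
    if (length(a) >= 2L && length(b) >= 2L) {
      labs <- c(rep("normal", length(a)), rep("tumor", length(b)))
      roc <- rocCurve(c(a, b), labs, "tumor")
      tt <- tTestGroups(a, b)
      out[["normal_vs_tumor"]] <- list(tTest = tt, roc = roc,
                                       n = c(length(a), length(b)))
      rows[["normal_vs_tumor"]] <- data.frame(
        pair = "normal_vs_tumor", metric = metric, positive = "tumor",
        n_a = length(a), n_b = length(b), t = tt$statistic,
        p_value = tt$p.value, auc = roc$auc,
        auc_oriented = max(roc$auc, 1 - roc$auc))
    }
  }
  out$summary <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
                 else data.frame()
  class(out) <- "GradeComparisonReport"
  out
}

#' @export
print.GradeComparisonReport <- function(x, ...) {
  cat("Grade comparison report (no multiple-testing correction)\n")
  if (!is.null(x$summary) && nrow(x$summary)) print(x$summary, row.names = FALSE)
  invisible(x)
}
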