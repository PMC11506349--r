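test_that("summaries report exact mean, max and min", {
  s <- summarizeValues(c(1, 2, 3))
  expect_equal(s, list(mean = 2, max = 3, min = 1))
  expect_equal(summarizeValues(7), list(mean = 7, max = 7, min = 7))
  set.seed(1)
  x <- rnorm(20)
  expect_equal(summarizeValues(x), summarizeValues(rev(x)))
  expect_error(summarizeValues(numeric(0)), "no finite")
})

test_that("Student's t-test matches the closed-form pooled statistic", {
  r <- tTestGroups(c(1, 2, 3), c(4, 5, 6))
  # pooled: mean diff -3, sp^2 = 1, se = sqrt(2/3), t = -3.6742, df = 4
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(r$df, 4)
  expect_equal(r$p.value, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(r$p.value, 0.0213, tolerance = 1e-3)
  # identical groups: t = 0, p = 1 by convention
  same <- tTestGroups(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # antisymmetry
  a <- rnorm(8); b <- rnorm(8, 1)
  r1 <- tTestGroups(a, b); r2 <- tTestGroups(b, a)
  expect_equal(r1$statistic, -r2$statistic)
  expect_equal(r1$p.value, r2$p.value)
  expect_error(tTestGroups(1, c(1, 2)), "at least 2")
})

test_that("pooled t statistic matches the closed form on random inputs", {
  set.seed(10)
  for (i in 1:25) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), sd = 2)
    na <- length(a); nb <- length(b)
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    tref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    expect_equal(tTestGroups(a, b)$statistic, tref, tolerance = 1e-10)
  }
})

test_that("ROC handles perfect separation and complete ties", {
  r <- rocCurve(c(0.7, 0.8, 0.9, 0.1, 0.2, 0.3),
                c("t", "t", "t", "n", "n", "n"), "t")
  expect_equal(r$auc, 1)
  tie <- rocCurve(rep(0.5, 6), c("t", "t", "t", "n", "n", "n"), "t")
  expect_equal(tie$auc, 0.5)
  expect_error(rocCurve(1:3, c("t", "t", "t"), "t"), "both classes")
})

test_that("ROC curve geometry is consistent with the U-statistic AUC", {
  set.seed(3)
  scores <- c(rnorm(15, 1), rnorm(12))
  labels <- rep(c("pos", "neg"), c(15, 12))
  r <- rocCurve(scores, labels, "pos")
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  trap <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
  expect_equal(trap, r$auc, tolerance = 1e-12)
})

test_that("AUC equals the ordered-pair oracle and pROC on random data", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    scores <- round(rnorm(n), sample(0:2, 1))   # induce ties
    labels <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r <- rocCurve(scores, labels, "b")
    expect_equal(r$auc, pairCountAUC(scores, labels, "b"), tolerance = 1e-12)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    scores <- rnorm(40); labels <- rep(c("a", "b"), 20)
    expect_equal(rocCurve(scores, labels, "b")$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                levels = c("a", "b"),
                                                direction = "<",
                                                quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("complementary scores give complementary AUC without ties", {
  set.seed(21)
  scores <- rnorm(30)   # continuous, no ties
  labels <- sample(c("x", "y"), 30, replace = TRUE, prob = c(0.4, 0.6))
  a1 <- rocCurve(scores, labels, "y")$auc
  a2 <- rocCurve(-scores, labels, "y")$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("grade comparison report covers all pairs and orients positives", {
  set.seed(5)
  tab <- data.frame(
    slide_id = rep(c("s1", "s2"), each = 15),
    field_or_window_id = sprintf("w%d", 1:30),
    grade_label = rep(c("normal", "poorly", "well"), each = 10),
    metric_name = "nc_ratio",
    value = c(rnorm(10, 0.01, 0.002), rnorm(10, 0.5, 0.05),
              rnorm(10, 0.1, 0.02)))
  rep <- gradeComparisonReport(tab, "nc_ratio", pooledTumor = TRUE)
  expect_setequal(setdiff(names(rep), "summary"),
                  c("normal_vs_poorly", "normal_vs_well", "poorly_vs_well",
                    "normal_vs_tumor"))
  expect_equal(rep$normal_vs_poorly$roc$positive, "poorly")
  expect_equal(rep$poorly_vs_well$roc$positive, "poorly")
  expect_equal(rep$normal_vs_poorly$roc$auc, 1)
  # missing grades are skipped, one warning per absent pair
  single <- tab[tab$grade_label == "well", ]
  w <- capture_warnings(r1 <- gradeComparisonReport(single, "nc_ratio"))
  expect_length(w, 3L)
  expect_true(all(grepl("skipped", w)))
  expect_equal(nrow(r1$summary), 0L)
})
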