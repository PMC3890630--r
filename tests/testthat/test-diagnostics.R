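rec <- function(t_mean, t_sd) data.frame(t_mean = t_mean, t_sd = t_sd)

test_that("the cutoff rule classifies group-typical lesions correctly", {
  either <- eus_rule(65, 75, "either")
  expect_equal(classify(rec(82.8, 83.5), either)$predicted_label, "GIST")
  expect_equal(classify(rec(39.8, 54.3), either)$predicted_label, "non-GIST")
  # boundary is inclusive
  expect_equal(classify(rec(65, 0), either)$predicted_label, "GIST")
  expect_equal(classify(rec(0, 75), either)$predicted_label, "GIST")

  expect_equal(classify(rec(70, 70), eus_rule(65, 75, "both"))$predicted_label,
               "non-GIST")
  expect_equal(classify(rec(70, 70), eus_rule(65, 75, "mean_only"))$predicted_label,
               "GIST")
  expect_equal(classify(rec(70, 70), eus_rule(65, 75, "sd_only"))$predicted_label,
               "non-GIST")
  expect_error(eus_rule(t_mean_cut = 300), "cutoffs")
})

test_that("confusion metrics reproduce hand-computed rates", {
  m <- evaluate(counts = c(tp = 47, fp = 3, fn = 3, tn = 12))
  est <- setNames(round(m$rates$estimate, 1), m$rates$rate)
  expect_equal(unname(est[c("sensitivity", "specificity", "ppv", "npv", "accuracy")]),
               c(94.0, 80.0, 94.0, 80.0, 90.8))

  perfect <- data.frame(truth_label = c("GIST", "non-GIST"),
                        predicted_label = c("GIST", "non-GIST"))
  expect_true(all(evaluate(perfect[rep(1:2, 10), ])$rates$estimate == 100))
})

test_that("metric identities hold exactly and zero denominators give NA", {
  set.seed(23)
  for (i in 1:25) {
    cts <- as.list(setNames(sample(0:40, 4, replace = TRUE),
                            c("tp", "fp", "fn", "tn")))
    m <- evaluate(counts = cts)
    est <- setNames(m$rates$estimate, m$rates$rate)
    chk <- function(nm, num, den) {
      if (den == 0) expect_true(is.na(est[[nm]]))
      else expect_equal(est[[nm]], 100 * num / den)
    }
    chk("sensitivity", cts$tp, cts$tp + cts$fn)
    chk("specificity", cts$tn, cts$tn + cts$fp)
    chk("ppv", cts$tp, cts$tp + cts$fp)
    chk("npv", cts$tn, cts$tn + cts$fn)
    chk("accuracy", cts$tp + cts$tn, Reduce(`+`, cts))
  }
})

test_that("Wilson intervals bracket the estimate within [0, 100]", {
  m <- evaluate(counts = c(tp = 43, fp = 1, fn = 7, tn = 14))
  r <- m$rates
  expect_true(all(r$ci_low >= 0 & r$ci_high <= 100))
  expect_true(all(r$ci_low <= r$estimate & r$estimate <= r$ci_high))
})

test_that("ROC handles separated, degenerate and simulated scores", {
  set.seed(101)
  sep <- data.frame(truth_label = rep(c("GIST", "non-GIST"), each = 20),
                    t_mean = c(runif(20, 150, 200), runif(20, 20, 60)))
  roc <- roc_analysis(sep, "t_mean")
  expect_equal(roc$auc, 1.0)
  expect_gt(roc$optimal_cutoff, max(sep$t_mean[sep$truth_label == "non-GIST"]))
  expect_lte(roc$optimal_cutoff, min(sep$t_mean[sep$truth_label == "GIST"]))

  same <- data.frame(truth_label = rep(c("GIST", "non-GIST"), each = 10),
                     t_mean = rep(100, 20))
  expect_equal(roc_analysis(same, "t_mean")$auc, 0.5)

  one_class <- data.frame(truth_label = rep("GIST", 5), t_mean = 1:5)
  expect_error(roc_analysis(one_class, "t_mean"), "both classes")

  coh <- generate_cohort(cohort_spec(n_gist = 5000, n_leiomyoma = 2500,
                                     n_schwannoma = 2500, seed = 31))
  best <- roc_analysis(coh, "t_mean")$optimal_cutoff
  expect_gte(best, 55)
  expect_lte(best, 75)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(27)
  d <- data.frame(truth_label = rep(c("GIST", "non-GIST"), each = 40),
                  t_mean = c(sample(40:110, 40, TRUE), sample(10:80, 40, TRUE)))
  a1 <- roc_analysis(d, "t_mean")$auc
  d2 <- d
  d2$t_mean <- 2 * d$t_mean + 10  # strictly monotone, still integer in [0,255]
  expect_equal(roc_analysis(d2, "t_mean")$auc, a1, tolerance = 1e-12)
})

test_that("integer-score AUC matches pROC's empirical AUC", {
  skip_if_not_installed("pROC")
  set.seed(29)
  d <- data.frame(truth_label = rep(c("GIST", "non-GIST"), c(60, 40)),
                  t_mean = c(sample(30:120, 60, TRUE), sample(0:90, 40, TRUE)))
  mine <- roc_analysis(d, "t_mean")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = d$truth_label == "GIST", predictor = d$t_mean, quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("one-way ANOVA matches hand computation and degenerate conventions", {
  res <- one_way_anova(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 13.5)
  expect_equal(res$df, c(1, 4))
  expect_equal(res$p_value, stats::pf(13.5, 1, 4, lower.tail = FALSE))

  const <- one_way_anova(list(rep(2, 3), rep(2, 3), rep(2, 3)))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
  expect_error(one_way_anova(list(1:3)), "groups")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(37)
  for (i in 1:10) {
    a <- rnorm(sample(5:20, 1), 50, 10)
    b <- rnorm(sample(5:20, 1), 55, 12)
    f <- one_way_anova(list(a, b))
    t <- compare_two_groups(a, b)
    expect_equal(f$statistic, t$statistic^2, tolerance = 1e-10)
    expect_equal(f$p_value, t$p_value, tolerance = 1e-10)
  }
})

test_that("two-group comparison handles identical and zero-variance inputs", {
  expect_equal(compare_two_groups(1:5, 1:5),
               list(statistic = 0, df = 8, p_value = 1))
  expect_warning(res <- compare_two_groups(rep(0, 4), rep(1, 4)), "variance")
  expect_lt(res$p_value, 1e-300)
  expect_error(compare_two_groups(1, 1:3), "values")
})

test_that("simulated benign vs malignant GIST groups stay non-significant", {
  set.seed(41)
  ps <- replicate(200, {
    compare_two_groups(rnorm(31, 88.2, 21.7), rnorm(14, 82.1, 23.0))$p_value
  })
  med <- median(ps)
  expect_gte(med, 0.15)
  expect_lte(med, 0.7)
})
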