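# ROC/AUC machinery, Youden points, confusion metrics, AUC-comparison tests,
# association tests and the logistic baseline.

test_that("AUC equals the tie-corrected pairwise Mann-Whitney statistic", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
  set.seed(42)
  for (r in 1:25) {
    n <- sample(10:60, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1)) # induce ties sometimes
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("ROC curves run (0,0) -> (1,1) monotonically and integrate to AUC", {
  set.seed(7)
  for (r in 1:10) {
    scores <- round(runif(40), 2)
    labels <- rbinom(40, 1, 0.35)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    rc <- roc_auc(scores, labels)
    expect_equal(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
    expect_equal(c(rc$fpr[length(rc$fpr)], rc$tpr[length(rc$tpr)]), c(1, 1))
    expect_true(all(diff(rc$tpr) >= 0) && all(diff(rc$fpr) >= 0))
    expect_true(all(diff(rc$thresholds) < 0))
    expect_equal(trapezoid_auc(rc), rc$auc, tolerance = 1e-12)
  }
})

test_that("Youden thresholds maximize J with ties to the smallest threshold", {
  # perfect separation: J = 1 at the midpoint between the classes
  yt <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(yt$j, 1)
  expect_equal(yt$threshold, 0.5)
  # two argmax thresholds: the smaller one wins
  yt2 <- youden_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(yt2$j, 0.5)
  expect_equal(yt2$threshold, 0.225)
  # constant scores: J = 0 at the low sentinel
  yt3 <- youden_threshold(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))
  expect_equal(yt3$j, 0)
  expect_equal(yt3$threshold, -Inf)
  # exhaustive-scan agreement on random fixtures
  set.seed(11)
  for (r in 1:10) {
    scores <- round(runif(30), 2)
    labels <- rbinom(30, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    yt <- youden_threshold(scores, labels)
    grid <- c(-Inf, sort(unique(scores)) - 1e-9, Inf)
    js <- vapply(grid, function(t) {
      mean(scores[labels == 1] >= t) + mean(scores[labels == 0] < t) - 1
    }, 0)
    expect_equal(yt$j, max(js), tolerance = 1e-9)
    expect_true(yt$j >= 0 && yt$j <= 1)
  }
})

test_that("confusion metrics match their definitions and flag 0/0 ratios", {
  scores <- c(rep(0.8, 3), 0.8, rep(0.2, 5), 0.2)
  labels <- c(rep(1, 3), 0, rep(0, 5), 1)   # TP=3 FP=1 TN=5 FN=1 at 0.5
  m <- confusion_metrics(scores, labels, 0.5)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 5 / 6)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 5 / 6)
  expect_equal(m$accuracy, 0.8)
  lo <- confusion_metrics(scores, labels, 0)     # everything positive
  expect_equal(lo$sensitivity, 1)
  expect_equal(lo$specificity, 0)
  expect_equal(lo$undefined, "npv")
  hi <- confusion_metrics(scores, labels, 2)     # everything negative
  expect_equal(hi$sensitivity, 0)
  expect_equal(hi$specificity, 1)
  expect_equal(hi$undefined, "ppv")
})

test_that("DeLong reduces to p = 1 on self-comparison and matches roc_auc", {
  set.seed(3)
  s <- runif(30)
  lab <- rbinom(30, 1, 0.5)
  lab[1:2] <- c(0L, 1L)
  d <- delong_test(s, s, lab)
  expect_equal(d$statistic, 0)
  expect_equal(d$p_value, 1)
  s2 <- runif(30)
  d2 <- delong_test(s, s2, lab)
  expect_equal(d2$auc_a, roc_auc(s, lab)$auc)
  expect_equal(d2$auc_b, roc_auc(s2, lab)$auc)
})

test_that("DeLong variance matches the O(n^2) placement oracle", {
  set.seed(5)
  for (r in 1:10) {
    n <- sample(12:30, 1)
    lab <- c(rep(0L, ceiling(n / 2)), rep(1L, floor(n / 2)))
    sa <- round(runif(n), 2)
    sb <- 0.5 * sa + 0.5 * runif(n)
    d <- delong_test(sa, sb, lab)
    o <- oracle_delong(sa, sb, lab)
    expect_equal(d$auc_a, o$auc_a, tolerance = 1e-12)
    expect_equal(d$var_diff, o$var_diff, tolerance = 1e-10)
    expect_equal(d$statistic, o$z, tolerance = 1e-8)
  }
})

test_that("DeLong agrees with an independent published implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  lab <- c(rep(0, 60), rep(1, 40))
  sa <- rnorm(100, mean = lab)
  sb <- rnorm(100, mean = 0.5 * lab)
  d <- delong_test(sa, sb, lab)
  ref <- pROC::roc.test(pROC::roc(lab, sa, quiet = TRUE),
                        pROC::roc(lab, sb, quiet = TRUE), method = "delong")
  expect_equal(d$p_value, unname(ref$p.value), tolerance = 1e-9)
})

test_that("bootstrap AUC test: null self-comparison, power, DeLong agreement", {
  set.seed(13)
  lab <- c(rep(0L, 100), rep(1L, 100))
  s <- runif(200)
  expect_equal(bootstrap_auc_test(s, s, lab, n_rep = 200, seed = 1)$p_value,
               1)
  strong <- rnorm(200, mean = 1.8 * lab)
  rand <- runif(200)
  hits <- vapply(1:10, function(sd)
    bootstrap_auc_test(strong, rand, lab, n_rep = 500, seed = sd)$p_value,
    0)
  expect_true(all(hits < 0.01))
  # moderate effects: bootstrap and DeLong p-values within 0.05
  sa <- rnorm(200, mean = 0.95 * lab)
  sb <- rnorm(200, mean = 0.55 * lab)
  pb <- bootstrap_auc_test(sa, sb, lab, n_rep = 2000, seed = 3)$p_value
  pd <- delong_test(sa, sb, lab)$p_value
  expect_lt(abs(pb - pd), 0.05)
})

test_that("association tests choose WMW / Kruskal-Wallis / chi-squared", {
  df <- data.frame(he4 = c(1, 2, 3, 4, 5, 6),
                   grp = c(0, 0, 0, 1, 1, 1))
  sch <- list(he4 = covariate_spec("he4", "quantitative"),
              grp = covariate_spec("grp", "binary"))
  co <- cohort(df, sch, c(0L, 1L, 0L, 1L, 0L, 1L), rep("all", 6))
  # exact enumeration: {1,2,3} vs {4,5,6} has one-sided tail 1/20
  t1 <- assoc_tests(co, "he4", "grp")
  expect_equal(t1$method, "wilcoxon-exact")
  expect_equal(t1$p_value, 0.1)
  # identical distributions: normal-approximation WMW centers at p = 1
  df2 <- data.frame(v = rep(c(1, 2, 3), 8), grp = rep(c(0, 1), 12))
  sch2 <- list(v = covariate_spec("v", "quantitative"),
               grp = covariate_spec("grp", "binary"))
  co2 <- cohort(df2, sch2, rep(c(0L, 1L), 12), rep("all", 24))
  t2 <- assoc_tests(co2, "v", "grp")
  expect_equal(t2$method, "wilcoxon-normal")
  expect_equal(t2$p_value, 1, tolerance = 1e-9)
  # > 2 groups: Kruskal-Wallis
  df3 <- data.frame(v = rnorm(30), g3 = rep(1:3, 10))
  sch3 <- list(v = covariate_spec("v", "quantitative"),
               g3 = covariate_spec("g3", "ordered", levels = c("a", "b", "c")))
  co3 <- cohort(df3, sch3, rep(c(0L, 1L), 15), rep("all", 30))
  expect_equal(assoc_tests(co3, "v", "g3")$method, "kruskal-wallis")
  # two categoricals: chi-squared without correction; balanced table -> p = 1
  df4 <- data.frame(a = rep(c(1, 2), each = 20), b = rep(c(1, 2), 20))
  sch4 <- list(a = covariate_spec("a", "binary", levels = c("x", "y")),
               b = covariate_spec("b", "binary", levels = c("u", "v")))
  co4 <- cohort(df4 - 1, sch4, rep(c(0L, 1L), 20), rep("all", 40))
  t4 <- assoc_tests(co4, "a", "b")
  expect_equal(t4$method, "chi-squared")
  expect_equal(t4$statistic, 0)
  expect_equal(t4$p_value, 1)
})

test_that("association tests drop missing rows and flag emptied groups", {
  df <- data.frame(v = c(1, 2, NA, NA, 5, 6), grp = c(0, 0, 0, 1, 1, 1))
  sch <- list(v = covariate_spec("v", "quantitative"),
              grp = covariate_spec("grp", "binary"))
  co <- cohort(df, sch, rep(c(0L, 1L), 3), rep("all", 6))
  expect_equal(assoc_tests(co, "v", "grp")$n_used, 4)
  df$v[c(5, 6)] <- NA
  co2 <- cohort(df, sch, rep(c(0L, 1L), 3), rep("all", 6))
  expect_error(assoc_tests(co2, "v", "grp"), "fewer than 2")
})

test_that("Pearson correlation handles affine, noisy and degenerate input", {
  expect_equal(pearson_correlation(1:10, 1:10)$rho, 1)
  expect_equal(pearson_correlation(1:10, -2 * (1:10) + 3)$rho, -1)
  pc <- pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(pc$rho, 0.8)
  expect_equal(pearson_correlation(c(1, NA, 3, 4, 5), c(2, 3, NA, 5, 7))$n_used,
               3)
  expect_equal(pearson_correlation(rep(1, 5), 1:5)$flag, "degenerate")
})

test_that("the logistic baseline matches closed-form fits and flags trouble", {
  # intercept-only: every score is the prevalence
  co <- make_cohort(data.frame(x = rep(1, 40)),
                    c(rep(1L, 10), rep(0L, 30)))
  lb <- logistic_baseline(co)
  expect_equal(lb$scores, rep(0.25, 40), tolerance = 1e-9)
  # single binary covariate: fitted odds ratio is the table cross-ratio
  tab <- c(a = 12, b = 18, c = 7, d = 23)
  x <- c(rep(1, tab["a"] + tab["b"]), rep(0, tab["c"] + tab["d"]))
  y <- c(rep(1, tab["a"]), rep(0, tab["b"]), rep(1, tab["c"]),
         rep(0, tab["d"]))
  sch <- list(x = covariate_spec("x", "binary"))
  co2 <- cohort(data.frame(x = x), sch, as.integer(y), rep("all", length(y)))
  lb2 <- logistic_baseline(co2)
  or_fit <- exp(coef(lb2$model)[["x"]])
  expect_equal(or_fit, (12 * 23) / (18 * 7), tolerance = 1e-8)
  # perfectly separable covariate raises the separation flag
  co3 <- make_cohort(data.frame(x = c(1:10, 21:30)),
                     c(rep(0L, 10), rep(1L, 10)))
  lb3 <- suppressWarnings(logistic_baseline(co3))
  expect_true(lb3$separation)
  # listwise deletion is counted
  df <- data.frame(x = c(NA, rnorm(29)))
  co4 <- make_cohort(df, rbinom(30, 1, 0.5))
  expect_equal(logistic_baseline(co4)$n_dropped, 1)
})
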