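test_that("threshold metrics reproduce the derived scores of all three cohorts", {
  # development: precision 0.44, recall 0.79, specificity 0.84
  d <- confusion_vectors(tp = 1738, fp = 2212, fn = 462, tn = 11613)
  m <- confusion_metrics(d$risks, d$labels, pt = 0.5)
  expect_equal(m$precision, 0.44, tolerance = 1e-12)
  expect_equal(m$recall, 0.79, tolerance = 1e-12)
  expect_equal(m$specificity, 0.84, tolerance = 1e-12)
  expect_lt(abs(m$f1 - 0.57), 0.00501)
  expect_lt(abs(m$f2 - 0.68), 0.00501)
  expect_lt(abs(m$balanced_accuracy - 0.82), 0.00501)

  # temporal: precision 0.47, recall 0.76, specificity 0.79
  d <- confusion_vectors(tp = 18753, fp = 21147, fn = 5922, tn = 79553)
  m <- confusion_metrics(d$risks, d$labels, pt = 0.5)
  expect_equal(m$precision, 0.47, tolerance = 1e-12)
  expect_equal(m$recall, 0.76, tolerance = 1e-12)
  expect_equal(m$specificity, 0.79, tolerance = 1e-12)
  expect_lt(abs(m$f1 - 0.58), 0.00501)
  expect_lt(abs(m$f2 - 0.68), 0.00501)
  expect_lt(abs(m$balanced_accuracy - 0.78), 0.00501)

  # external: precision 0.48, recall 0.73, specificity 0.86
  d <- confusion_vectors(tp = 6132, fp = 6643, fn = 2268, tn = 40807)
  m <- confusion_metrics(d$risks, d$labels, pt = 0.5)
  expect_equal(m$precision, 0.48, tolerance = 1e-12)
  expect_equal(m$recall, 0.73, tolerance = 1e-12)
  expect_equal(m$specificity, 0.86, tolerance = 1e-12)
  expect_lt(abs(m$f1 - 0.58), 0.00501)
  expect_lt(abs(m$f2 - 0.66), 0.00501)
  expect_lt(abs(m$balanced_accuracy - 0.80), 0.00501)
})

test_that("degenerate confusion inputs are flagged, not zeroed", {
  m <- confusion_metrics(c(0.1, 0.2), c(0, 1), pt = 0.5)
  expect_true(is.na(m$precision))
  expect_true("precision" %in% m$undefined)
  mp <- confusion_metrics(c(0.9, 0.9, 0.1, 0.2), c(1, 1, 0, 0), pt = 0.5)
  expect_equal(mp$recall, 1); expect_equal(mp$specificity, 1)
  expect_equal(mp$mcc, 1); expect_equal(mp$f1, 1)
  expect_lt(mp$brier, 0.02)
})

test_that("rank metrics match exhaustive pair counting and behave under reversal", {
  set.seed(2)
  risks <- round(runif(60), 1)   # forces ties
  labels <- rbinom(60, 1, 0.4)
  rm_ <- rank_metrics(risks, labels)
  expect_equal(rm_$auc, oracle_auc(risks, labels), tolerance = 1e-12)
  rev_ <- rank_metrics(1 - risks, labels)
  expect_equal(rev_$auc, 1 - rm_$auc, tolerance = 1e-12)
  # random scores on balanced labels sit near one half
  set.seed(3)
  big <- rank_metrics(runif(1e4), rbinom(1e4, 1, 0.5))
  expect_gt(big$auc, 0.48); expect_lt(big$auc, 0.52)
  expect_error(rank_metrics(runif(5), rep(1, 5)), "both classes")
  # perfect ranking: AUC and AUPRC are 1
  perf <- rank_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perf$auc, 1); expect_equal(perf$auprc, 1)
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  risks <- runif(300); labels <- rbinom(300, 1, plogis(2 * risks - 1))
  expect_equal(rank_metrics(risks, labels)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, risks, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("clustered bootstrap is deterministic and degenerate-aware", {
  d <- data.frame(x = rnorm(40), cl = rep(1:8, each = 5))
  st <- function(df) mean(df$x)
  b1 <- cluster_bootstrap(st, d, d$cl, B = 100, seed = 7)
  b2 <- cluster_bootstrap(st, d, d$cl, B = 100, seed = 7)
  expect_identical(b1, b2)
  expect_true(b1$lower <= b1$est && b1$est <= b1$upper)
  one <- cluster_bootstrap(st, d[d$cl == 1, ], rep(1, 5), B = 50, seed = 1)
  expect_true(one$degenerate)
  expect_equal(one$lower, one$upper)
  expect_equal(one$lower, one$est)
})

test_that("calibration suite honors its closed forms", {
  # constant risk equal to prevalence: CITL 0, ECE 0, Brier pi(1-pi)
  y <- rep(c(0, 1), c(75, 25))
  p <- rep(0.25, 100)
  cs <- calibration_suite(p, y)
  expect_equal(cs$citl, 0, tolerance = 1e-8)
  expect_equal(cs$ece, 0, tolerance = 1e-12)
  expect_equal(cs$brier, 0.25 * 0.75, tolerance = 1e-12)
  # well-specified risks at large n: slope 1, intercept 0, small ECE
  set.seed(5)
  n <- 5e4
  p <- plogis(rnorm(n, -1, 1))
  y <- rbinom(n, 1, p)
  cs <- calibration_suite(p, y)
  expect_lt(abs(cs$slope - 1), 0.05)
  expect_lt(abs(cs$citl), 0.05)
  expect_lt(cs$ece, 0.02)
  expect_warning(calibration_suite(c(0, 0.5, 1), c(0, 1, 1)), "clipped")
})

test_that("net benefit arithmetic matches the decision-analytic identities", {
  expect_equal(round(0.125 / (1 - 0.125), 3), 0.143)
  expect_equal(round(nb_treat_all(0.171, 0.125), 3), 0.053)
  expect_equal(round(nb_treat_all(0.142, 0.125), 3), 0.019)
  # limits: pt -> 0 gives prevalence / TP share
  y <- rbinom(500, 1, 0.3); r <- runif(500)
  expect_equal(nb_treat_all(mean(y), 1e-9), mean(y), tolerance = 1e-6)
  expect_equal(net_benefit(rep(1, 500), y, 1e-9), mean(y), tolerance = 1e-6)
  # NB never exceeds prevalence
  for (pt in c(0.05, 0.125, 0.3)) {
    expect_lte(net_benefit(r, y, pt), mean(y))
  }
  # a perfect predictor dominates treat-all and treat-none at interior pts
  rp <- ifelse(y == 1, 0.99, 0.01)
  d <- dca_curve(rp, y, pt_grid = seq(0.05, 0.45, 0.05))
  expect_true(all(d$nb_model >= d$nb_all - 1e-12))
  expect_true(all(d$nb_model >= 0))
  expect_error(net_benefit(r, y, 1.2), "\\(0, 1\\)")
})

test_that("DeLong comparison matches brute-force placements and pROC", {
  set.seed(6)
  r1 <- runif(80); l1 <- rbinom(80, 1, plogis(2 * r1 - 1))
  r2 <- runif(70); l2 <- rbinom(70, 1, plogis(r2))
  dc <- delong_compare(r1, l1, r2, l2)
  o1 <- oracle_placements(r1, l1)
  expect_equal(dc$auc1, o1$auc, tolerance = 1e-12)
  expect_equal(dc$var1, var(o1$v10) / length(o1$v10) +
                 var(o1$v01) / length(o1$v01), tolerance = 1e-12)
  # identical groups: zero difference, p = 1
  same <- delong_compare(r1, l1, r1, l1)
  expect_equal(same$auc1, same$auc2)
  expect_equal(same$p, 1)
  # Bonferroni multiplies and caps
  expect_equal(delong_compare(r1, l1, r2, l2, m_comparisons = 20)$p_bonferroni,
               min(1, 20 * dc$p))
  skip_if_not_installed("pROC")
  rt <- pROC::roc.test(pROC::roc(l1, r1, quiet = TRUE),
                       pROC::roc(l2, r2, quiet = TRUE),
                       method = "delong", paired = FALSE)
  # pROC refers the same statistic to a t distribution; compare the statistic
  expect_equal(dc$z, unname(rt$statistic), tolerance = 1e-9)
})

test_that("standardized mean differences follow their closed forms", {
  x <- rnorm(500)
  expect_equal(asmd(x, x), 0)
  expect_equal(asmd(rep(c(0, 1), 50), rep(c(0, 1), 80)), 0)
  set.seed(9)
  a <- rnorm(2e5, 0, 1); b <- rnorm(2e5, 1, 1)
  expect_equal(asmd(a, b), 1.0, tolerance = 0.02)
  expect_warning(v <- asmd(rep(1, 5), rep(2, 5)), "infinite")
  expect_true(is.infinite(v))
  expect_equal(asmd(rep(1, 5), rep(1, 8)), 0)
  # missing values are ignored
  expect_equal(asmd(c(a, NA, NA), b), asmd(a, b))
})

test_that("bootstrap CIs narrow as the number of clusters grows", {
  set.seed(10)
  widths <- sapply(c(10, 40, 160), function(ncl) {
    d <- data.frame(x = rnorm(ncl * 5), cl = rep(seq_len(ncl), each = 5))
    b <- cluster_bootstrap(function(df) mean(df$x), d, d$cl, B = 200, seed = 2)
    b$upper - b$lower
  })
  expect_true(all(diff(widths) < 0))
})
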