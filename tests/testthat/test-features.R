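test_that("window summaries follow their closed forms", {
  st <- data.frame(time = c(10, 11), value = c(5, 7))
  expect_equal(summarize_window(st, 12, "slope", 12), 2.0)
  st1 <- data.frame(time = 10, value = 4.2)
  expect_equal(summarize_window(st1, 12, "mean", 12), 4.2)
  expect_true(is.na(summarize_window(st1, 12, "slope", 12)))
  expect_true(is.na(summarize_window(st1, 12, "sd", 12)))
  # only points strictly before the cutoff and within the lookback count
  st2 <- data.frame(time = c(-1, 0, 6, 12), value = c(99, 1, 2, 99))
  expect_equal(summarize_window(st2, 12, "mean", 12), 1.5)
  expect_equal(summarize_window(st2, 12, "max", 12), 2)
})

test_that("OLS slopes agree with lm on noisy series", {
  set.seed(1)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    t <- sort(runif(n, 0, 48))
    y <- 0.3 * t + rnorm(n)
    st <- data.frame(time = t, value = y)
    expect_equal(summarize_window(st, 48, "slope", 48),
                 unname(coef(lm(y ~ t))[2]), tolerance = 1e-10)
  }
})

test_that("piecewise slope change recovers planted breaks and degenerates safely", {
  # perfectly linear: no slope change
  st <- data.frame(time = 0:9, value = 2 * (0:9) + 1)
  expect_equal(piecewise_slope_change(st, 10, 12), 0, tolerance = 1e-8)
  # slope 0 then slope -2 from the midpoint
  t <- 0:10
  y <- ifelse(t <= 5, 3, 3 - 2 * (t - 5))
  expect_equal(piecewise_slope_change(data.frame(time = t, value = y), 11, 12),
               -2, tolerance = 1e-8)
  # fewer than 4 points
  expect_true(is.na(piecewise_slope_change(
    data.frame(time = 1:3, value = 1:3), 4, 12)))
})

test_that("piecewise fits match an exhaustive lm-based breakpoint search", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    t <- sort(runif(n, 0, 48))
    b <- runif(1, 12, 36)
    y <- 1 + 0.2 * t + rnorm(1, 0, 1) * pmax(t - b, 0) + rnorm(n, 0, 0.3)
    got <- piecewise_slope_change(data.frame(time = t, value = y), 48, 48)
    expect_equal(got, oracle_psc(t, y), tolerance = 1e-6)
  }
})

test_that("feature screening drops by missingness and variance, reports collinearity", {
  set.seed(3)
  n <- 200
  X <- data.table::data.table(
    ok = rnorm(n),
    mostly_missing = ifelse(runif(n) < 0.6, NA_real_, rnorm(n)),
    constant = rep(1, n),
    near_constant = c(rep(0, 199), 1),
    dup_a = rnorm(n))
  X[, dup_b := dup_a]
  train <- rep(TRUE, n)
  s <- screen_features(X, names(X), train)
  expect_false("mostly_missing" %in% s$retained)
  expect_false("constant" %in% s$retained)
  expect_false("near_constant" %in% s$retained)
  expect_true(all(c("ok", "dup_a", "dup_b") %in% s$retained))
  hit <- s$collinearity[(f1 == "dup_a" & f2 == "dup_b") |
                          (f1 == "dup_b" & f2 == "dup_a")]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$pearson, 1.0)
  expect_error(screen_features(X, names(X), rep(FALSE, n)), "empty")
  # screening decisions ignore non-training rows
  X2 <- data.table::copy(X)
  X2[101:200, ok := NA_real_]
  s2 <- screen_features(X2, names(X2), c(rep(TRUE, 100), rep(FALSE, 100)))
  expect_true("ok" %in% s2$retained)
})

test_that("one-hot encoding learns vocabularies on training rows only", {
  X <- data.table::data.table(
    window_id = as.character(1:6), patient_id = "P", stay_id = "S",
    unit = c("MICU", "SICU", "CCU", "MICU", "SICU", "NeuroICU"),
    flag = c(0, 1, 0, 1, 0, 1))
  enc <- encode_categoricals(X, train_mask = c(rep(TRUE, 5), FALSE))
  expect_setequal(setdiff(names(enc$X), c("window_id", "patient_id",
                                          "stay_id", "flag")),
                  c("unit_MICU", "unit_SICU", "unit_CCU"))
  # unseen validation level maps to all-zero indicators
  expect_equal(unlist(enc$X[6, .(unit_MICU, unit_SICU, unit_CCU)]),
               c(unit_MICU = 0, unit_SICU = 0, unit_CCU = 0))
  # binary 0/1 columns pass through untouched
  expect_equal(enc$X$flag, X$flag)
  # a stored vocabulary reapplies identically
  enc2 <- encode_categoricals(X, vocab = enc$vocab)
  expect_identical(as.data.frame(enc2$X), as.data.frame(enc$X))
})

test_that("window features are causal in the cutoff", {
  co <- small_cohort()$cohort
  on <- aki_onsets(co)
  ex <- apply_exclusions(co, on)
  w <- build_cohort_windows(ex$stays, on)[1:40]
  X1 <- build_feature_matrix(co, w)
  co2 <- co
  # corrupt every measurement at or after each stay's smallest cutoff + eps:
  # features for windows at that cutoff must not move
  cut_min <- min(w$cutoff)
  co2$labs <- data.table::copy(co$labs)[time >= cut_min, value := value * 10]
  co2$vitals <- data.table::copy(co$vitals)[time >= cut_min, value := value + 50]
  co2$urine_output <- data.table::copy(co$urine_output)[time >= cut_min,
                                                        volume_ml := 0]
  X2 <- build_feature_matrix(co2, w)
  sel <- X1$cutoff == cut_min
  feature_cols <- setdiff(names(X1), c("window_id", "patient_id", "stay_id",
                                       "cutoff", "label"))
  expect_identical(as.data.frame(X1[sel, ..feature_cols]),
                   as.data.frame(X2[sel, ..feature_cols]))
})
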