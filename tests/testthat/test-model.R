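# A small synthetic tabular problem with patient clustering: five
# informative features drive the log-odds, the rest are noise.
make_tabular <- function(n_pat = 120, per_pat = 4, p_noise = 20, seed = 1,
                         beta = c(1.2, -1.0, 0.8, 0.9, -0.7)) {
  set.seed(seed)
  n <- n_pat * per_pat
  inf <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("inf", 1:5)))
  noise <- matrix(rnorm(n * p_noise), n, p_noise,
                  dimnames = list(NULL, paste0("noise", 1:p_noise)))
  eta <- inf %*% beta - 0.8
  y <- rbinom(n, 1, plogis(eta))
  X <- data.table::data.table(window_id = as.character(seq_len(n)),
                              patient_id = rep(sprintf("P%03d", seq_len(n_pat)),
                                               each = per_pat))
  X <- cbind(X, data.table::as.data.table(inf),
             data.table::as.data.table(noise))
  folds <- assign_folds(X, k = 4, seed = seed)
  list(X = X, y = y, folds = folds,
       features = c(colnames(inf), colnames(noise)))
}

test_that("a one-point grid wins trivially and training is seed-deterministic", {
  d <- make_tabular(n_pat = 60, p_noise = 5)
  g <- list(list(max_depth = 3, eta = 0.2, subsample = 1,
                 colsample_bytree = 1, min_child_weight = 1))
  b1 <- tune_and_train(d$X, d$features, d$y, d$folds, grid = g,
                       constraints = NULL, nrounds = 30, seed = 5)
  expect_equal(nrow(b1$grid_results), 1L)
  expect_equal(b1$params, g[[1]])
  b2 <- tune_and_train(d$X, d$features, d$y, d$folds, grid = g,
                       constraints = NULL, nrounds = 30, seed = 5)
  expect_equal(b1$oof$raw, b2$oof$raw)
  expect_equal(b1$cv_auc, b2$cv_auc)
})

test_that("single-class folds are rejected with the fold named", {
  d <- make_tabular(n_pat = 12, per_pat = 1, p_noise = 2)
  y <- d$y; y[d$folds == 2] <- 0
  expect_error(tune_and_train(d$X, d$features, y, d$folds,
                              grid = default_grid()[1], constraints = NULL,
                              nrounds = 10),
               "fold 2")
})

test_that("permuting a validation fold's labels leaves its predictions unchanged", {
  d <- make_tabular(n_pat = 60, p_noise = 5, seed = 11)
  g <- list(list(max_depth = 3, eta = 0.2, subsample = 1,
                 colsample_bytree = 1, min_child_weight = 1))
  b1 <- tune_and_train(d$X, d$features, d$y, d$folds, grid = g,
                       constraints = NULL, nrounds = 25, seed = 3)
  k <- 2
  y2 <- d$y
  idx <- which(d$folds == k)
  set.seed(99)
  y2[idx] <- sample(y2[idx])
  b2 <- tune_and_train(d$X, d$features, y2, d$folds, grid = g,
                       constraints = NULL, nrounds = 25, seed = 3)
  expect_equal(b1$oof$raw[idx], b2$oof$raw[idx])
})

test_that("monotone constraints are honored along feature sweeps", {
  set.seed(21)
  n <- 600
  X <- data.table::data.table(
    window_id = as.character(1:n),
    patient_id = sprintf("P%03d", rep(1:150, each = 4)),
    creatinine_last_72 = rlnorm(n, 0, 0.4),
    uo_rate_6 = pmax(rnorm(n, 1.2, 0.4), 0.05),
    other = rnorm(n))
  y <- rbinom(n, 1, plogis(1.5 * log(X$creatinine_last_72) -
                             1.2 * X$uo_rate_6 + 0.4 * X$other))
  feats <- c("creatinine_last_72", "uo_rate_6", "other")
  folds <- assign_folds(X, k = 3, seed = 1)
  cons <- default_constraints(feats)
  expect_equal(unname(cons), c(1L, -1L, 0L))
  b <- tune_and_train(X, feats, y, folds, grid = default_grid()[1],
                      constraints = cons, nrounds = 60, seed = 1)
  rep_ <- enforce_monotone(b, X, n_rows = 50, n_grid = 20, seed = 2)
  expect_equal(nrow(rep_), 0L)
})

test_that("SHAP selection keeps planted informative features at small AUC cost", {
  d <- make_tabular(n_pat = 150, per_pat = 4, p_noise = 50, seed = 13)
  b <- tune_and_train(d$X, d$features, d$y, d$folds, grid = default_grid()[1],
                      constraints = NULL, nrounds = 80, seed = 13)
  sel <- shap_select(b, d$X, d$y, k = 10)
  expect_true(all(paste0("inf", 1:5) %in% sel$features))
  expect_gte(sel$delta$auc_selected, sel$delta$auc_full - 0.02)
  # identity selection returns the same model
  sel_all <- shap_select(b, d$X, d$y, k = length(d$features))
  expect_identical(sel_all$bundle, b)
  expect_equal(sel_all$delta$delta_auc, 0)
  expect_error(shap_select(b, d$X, d$y, k = 999), "exceeds")
})

test_that("Platt scaling recovers calibrated inputs and is idempotent", {
  set.seed(8)
  n <- 50000
  p <- plogis(rnorm(n, -1.5, 1.2))
  y <- rbinom(n, 1, p)
  ab <- platt_fit(p, y)
  expect_gt(ab[["b"]], 0.9); expect_lt(ab[["b"]], 1.1)
  expect_gt(ab[["a"]], -0.1); expect_lt(ab[["a"]], 0.1)
  # refit on recalibrated output: slope ~ 1
  rec <- platt_apply(p, ab)
  ab2 <- platt_fit(rec, y)
  expect_gt(ab2[["b"]], 0.95); expect_lt(ab2[["b"]], 1.05)
  # constant raw risk maps to the observed prevalence
  ab3 <- platt_fit(rep(0.5, 400), rep(c(0, 1), c(300, 100)))
  expect_equal(unname(platt_apply(0.5, ab3)), 0.25, tolerance = 1e-8)
  expect_error(platt_fit(runif(10), rep(1, 10)), "both classes")
})

test_that("threshold choice maximizes F-beta with ties to the smaller cut", {
  # perfectly separated risks: the smallest positive risk wins with F2 = 1
  risks <- c(0.9, 0.8, 0.7, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0)
  pt <- choose_threshold(risks, labels)
  expect_equal(pt, 0.7)
  expect_equal(confusion_metrics(risks, labels, pt)$f2, 1)

  # brute-force scan oracle
  set.seed(31)
  risks <- round(runif(300), 2)
  labels <- rbinom(300, 1, plogis(3 * risks - 2))
  fbeta_at <- function(thr, beta = 2) {
    tp <- sum(risks >= thr & labels == 1); fp <- sum(risks >= thr & labels == 0)
    fn <- sum(risks < thr & labels == 1)
    if (tp + fp == 0) return(0)
    pr <- tp / (tp + fp); rc <- tp / (tp + fn)
    if (pr + rc == 0) return(0)
    (1 + beta^2) * pr * rc / (beta^2 * pr + rc)
  }
  cand <- sort(unique(risks))
  best <- max(vapply(cand, fbeta_at, numeric(1)))
  pt <- choose_threshold(risks, labels, beta = 2)
  expect_equal(fbeta_at(pt), best, tolerance = 1e-12)
  expect_equal(pt, min(cand[vapply(cand, fbeta_at, numeric(1)) >= best - 1e-12]))

  # sensitivity weighting: the F2 threshold never exceeds the F1 threshold
  pt_f1 <- choose_threshold(risks, labels, beta = 1)
  expect_lte(pt, pt_f1)
  expect_error(choose_threshold(runif(5), rep(0, 5)), "both classes")
})
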