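# Monotonicity-constrained gradient boosting with patient-grouped CV,
# SHAP-ranked feature selection, Platt recalibration and F-beta threshold
# selection. The learner is xgboost (native NA handling, per-feature
# monotone constraints); everything around it is defined here.

#' Default monotone constraint map
#'
#' +1 (risk non-decreasing) for creatinine, BUN and vasopressor-dose
#' features; -1 (non-increasing) for urine-output features; 0 otherwise.
#'
#' @param feature_names Character vector of feature column names.
#' @return Named integer vector in `{-1, 0, +1}`.
#' @export
default_constraints <- function(feature_names) {
  cons <- setNames(integer(length(feature_names)), feature_names)
  cons[grepl("^(creatinine|bun)_", feature_names)] <- 1L
  cons[grepl("^vaso_", feature_names)] <- 1L
  cons[grepl("^uo_", feature_names)] <- -1L
  cons
}

#' Default hyperparameter grid
#'
#' A small grid over tree depth and learning rate; each point carries
#' subsampling and minimum child weight. Tree count is governed by early
#' stopping on out-of-fold log-loss.
#'
#' @return List of named parameter lists.
#' @export
default_grid <- function() {
  list(
    list(max_depth = 4, eta = 0.1, subsample = 0.8, colsample_bytree = 0.8,
         min_child_weight = 5),
    list(max_depth = 6, eta = 0.1, subsample = 0.8, colsample_bytree = 0.8,
         min_child_weight = 5)
  )
}

as_dmatrix <- function(X, feature_names, label = NULL) {
  M <- as.matrix(X[, feature_names, with = FALSE])
  storage.mode(M) <- "double"
  if (is.null(label)) xgboost::xgb.DMatrix(M, missing = NA)
  else xgboost::xgb.DMatrix(M, label = label, missing = NA)
}

#' Grid search and patient-grouped cross-validated training
#'
#' For every grid point, trains one booster per fold and scores the pooled
#' out-of-fold predictions; the grid point with the highest mean
#' out-of-fold AUC wins. Per-fold models for the winner provide the
#' out-of-fold prediction table, and a final booster is refit on all rows.
#' By default the tree count is fixed (no early stopping), so a fold's
#' model never depends on its own held-out labels; optional early stopping
#' on the held-out fold's log-loss trades that guarantee for speed.
#'
#' @param X Feature matrix (data.table including feature columns).
#' @param feature_names Feature columns to use.
#' @param label 0/1 outcome vector.
#' @param folds Integer fold vector (patient-grouped, from
#'   [assign_folds()]).
#' @param grid List of parameter lists ([default_grid()]).
#' @param constraints Named direction vector ([default_constraints()]);
#'   `NULL` disables constraints.
#' @param nrounds Boosting rounds.
#' @param early_stopping Early-stopping patience in rounds; `NULL`
#'   (default) disables early stopping.
#' @param seed Seed controlling booster randomness.
#' @return Object of class `aki_model`: list with `booster`, `params`,
#'   `nrounds`, `feature_names`, `constraints`, `fold_models`, `oof`
#'   (data.table `window_id`, `raw`, `fold`, `label`, `patient_id`),
#'   `cv_auc`, `grid_results`, `platt` (NULL until fitted), `pt` (NA until
#'   chosen).
#' @export
tune_and_train <- function(X, feature_names, label, folds,
                           grid = default_grid(),
                           constraints = default_constraints(feature_names),
                           nrounds = 200L, early_stopping = NULL, seed = 1L) {
  if (!length(grid)) stopf("grid must be non-empty")
  ks <- sort(unique(folds))
  for (k in ks) {
    if (length(unique(label[folds != k])) < 2L)
      stopf("training rows for fold %s contain a single class", k)
    if (length(unique(label[folds == k])) < 2L)
      stopf("validation fold %s contains a single class", k)
  }
  cons_vec <- if (is.null(constraints)) NULL else
    as.integer(constraints[feature_names])

  dm_all <- as_dmatrix(X, feature_names, label)
  run_point <- function(pars) {
    fold_models <- vector("list", length(ks))
    oof <- rep(NA_real_, nrow(X))
    best_iters <- integer(length(ks))
    aucs <- numeric(length(ks))
    for (i in seq_along(ks)) {
      k <- ks[i]
      tr <- which(folds != k); va <- which(folds == k)
      dtr <- xgboost::xgb.DMatrix(
        as.matrix(X[tr, feature_names, with = FALSE]), label = label[tr],
        missing = NA)
      dva <- xgboost::xgb.DMatrix(
        as.matrix(X[va, feature_names, with = FALSE]), label = label[va],
        missing = NA)
      params <- c(pars, list(objective = "binary:logistic",
                             eval_metric = "logloss", nthread = 1,
                             seed = seed))
      if (!is.null(cons_vec)) params$monotone_constraints <- cons_vec
      bst <- if (is.null(early_stopping)) {
        xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds,
                           verbose = 0)
      } else {
        xgboost::xgb.train(params = params, data = dtr, nrounds = nrounds,
                           evals = list(val = dva),
                           early_stopping_rounds = early_stopping,
                           verbose = 0)
      }
      bi <- xgboost::xgb.attributes(bst)$best_iteration
      best_iters[i] <- if (is.null(bi)) nrounds else max(1L, as.integer(bi))
      fold_models[[i]] <- bst
      oof[va] <- predict(bst, dva)
      aucs[i] <- rank_metrics(oof[va], label[va])$auc
    }
    list(fold_models = fold_models, oof = oof, best_iters = best_iters,
         mean_auc = mean(aucs), fold_aucs = aucs)
  }

  results <- lapply(grid, run_point)
  mean_aucs <- vapply(results, `[[`, numeric(1), "mean_auc")
  win <- which.max(mean_aucs)
  res <- results[[win]]

  final_rounds <- max(1L, as.integer(round(median(res$best_iters))))
  params <- c(grid[[win]], list(objective = "binary:logistic",
                                eval_metric = "logloss", nthread = 1,
                                seed = seed))
  if (!is.null(cons_vec)) params$monotone_constraints <- cons_vec
  booster <- xgboost::xgb.train(params = params, data = dm_all,
                                nrounds = final_rounds, verbose = 0)

  oof_dt <- data.table(window_id = X$window_id, raw = res$oof,
                       fold = folds, label = label,
                       patient_id = X$patient_id)
  structure(list(
    booster = booster, params = grid[[win]], nrounds = final_rounds,
    feature_names = feature_names, constraints = constraints,
    fold_models = res$fold_models, folds = folds, oof = oof_dt,
    cv_auc = res$mean_auc,
    grid_results = data.table(point = seq_along(grid), mean_oof_auc = mean_aucs),
    platt = NULL, pt = NA_real_, seed = seed
  ), class = "aki_model")
}

#' @export
print.aki_model <- function(x, ...) {
  cat(sprintf("<aki_model> %d features, %d rounds, mean OOF AUC %.3f\n",
              length(x$feature_names), x$nrounds, x$cv_auc))
  invisible(x)
}

#' Verify monotone constraints by grid sweeps
#'
#' For each constrained feature, sweeps its value over a grid spanning the
#' observed range on a sample of rows (all other features fixed) and checks
#' that predicted risk moves in the constrained direction.
#'
#' @param bundle An `aki_model`.
#' @param X Feature matrix to sample sweep rows from.
#' @param n_rows Rows per feature sweep.
#' @param n_grid Grid points per sweep.
#' @param seed Sampling seed.
#' @param tol Numerical tolerance on violations.
#' @return data.table report (`feature`, `direction`, `n_violations`,
#'   `worst`); zero rows of violations means the constraints hold.
#' @export
enforce_monotone <- function(bundle, X, n_rows = 50L, n_grid = 20L,
                             seed = 1L, tol = 1e-9) {
  cons <- bundle$constraints
  if (is.null(cons)) return(data.table(feature = character(),
                                       direction = integer(),
                                       n_violations = integer(),
                                       worst = numeric()))
  cons <- cons[cons != 0]
  set.seed(seed)
  rows <- X[sample(seq_len(nrow(X)), min(n_rows, nrow(X)))]
  out <- list()
  for (f in names(cons)) {
    v <- X[[f]]
    rng <- range(v, na.rm = TRUE)
    if (!all(is.finite(rng)) || diff(rng) == 0) next
    gridv <- seq(rng[1], rng[2], length.out = n_grid)
    swept <- rows[rep(seq_len(nrow(rows)), each = n_grid)]
    set(swept, j = f, value = rep(gridv, times = nrow(rows)))
    p <- predict(bundle$booster, as_dmatrix(swept, bundle$feature_names))
    pm <- matrix(p, nrow = n_grid)
    d <- diff(pm) * cons[[f]]
    out[[f]] <- data.table(feature = f, direction = cons[[f]],
                           n_violations = sum(d < -tol),
                           worst = min(d))
  }
  rep_dt <- rbindlist(out)
  rep_dt[n_violations > 0]
}

#' SHAP-ranked feature selection and refit
#'
#' Ranks features by mean absolute SHAP value over out-of-fold rows (each
#' fold's model explains its own held-out rows; fold means are pooled by
#' simple average), keeps the top `k`, refits with the winning
#' hyperparameters, and reports the change in out-of-fold AUC.
#'
#' @param bundle Trained `aki_model` (with fold models).
#' @param X Feature matrix used for training.
#' @param label Outcome vector.
#' @param k Number of features to keep (default 61).
#' @return List `features` (selected names), `bundle` (retrained
#'   `aki_model`), `ranking` (data.table `feature`, `mean_abs_shap`),
#'   `delta` (list `auc_full`, `auc_selected`, `delta_auc`).
#' @export
shap_select <- function(bundle, X, label, k = 61L) {
  fn <- bundle$feature_names
  if (k > length(fn)) stopf("k (%d) exceeds available features (%d)", k, length(fn))
  ks <- sort(unique(bundle$folds))
  shap_sum <- matrix(0, nrow = length(ks), ncol = length(fn),
                     dimnames = list(NULL, fn))
  for (i in seq_along(ks)) {
    va <- which(bundle$folds == ks[i])
    dva <- as_dmatrix(X[va], fn)
    contrib <- predict(bundle$fold_models[[i]], dva, predcontrib = TRUE)
    shap_sum[i, ] <- colMeans(abs(contrib[, fn, drop = FALSE]))
  }
  ranking <- data.table(feature = fn, mean_abs_shap = colMeans(shap_sum))
  setorder(ranking, -mean_abs_shap)
  selected <- ranking$feature[seq_len(k)]

  if (k == length(fn)) {
    new_bundle <- bundle
  } else {
    new_bundle <- tune_and_train(
      X, selected, label, bundle$folds, grid = list(bundle$params),
      constraints = if (is.null(bundle$constraints)) NULL else
        bundle$constraints[selected],
      seed = bundle$seed)
  }
  auc_full <- rank_metrics(bundle$oof$raw, label)$auc
  auc_sel <- rank_metrics(new_bundle$oof$raw, label)$auc
  list(features = selected, bundle = new_bundle, ranking = ranking,
       delta = list(auc_full = auc_full, auc_selected = auc_sel,
                    delta_auc = auc_sel - auc_full))
}

# Ridge-penalized 2-parameter logistic fit (Newton), used when the plain
# ML fit separates.
ridge_logistic <- function(l, y, lambda = 1e-3, iters = 50L) {
  b <- c(0, 1)
  Xm <- cbind(1, l)
  for (i in seq_len(iters)) {
    eta <- Xm %*% b
    p <- plogis(eta)
    W <- as.numeric(p * (1 - p))
    g <- crossprod(Xm, y - p) - lambda * b
    H <- crossprod(Xm * W, Xm) + diag(lambda, 2)
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-10) break
  }
  c(a = b[1], b = b[2])
}

#' Fit Platt recalibration on out-of-fold predictions
#'
#' Logistic regression of the label on the logit of the raw predicted
#' probability: `recalibrated = plogis(a + b * qlogis(raw))`. Operating on
#' the logit of the probability makes the map idempotent (refitting on
#' already-recalibrated output returns slope ~ 1).
#'
#' @param raw Raw predicted probabilities.
#' @param label 0/1 outcomes.
#' @return Named vector `c(a, b)`.
#' @export
platt_fit <- function(raw, label) {
  if (length(unique(label)) < 2L) stopf("labels must contain both classes")
  l <- qlogis(clip_prob(raw))
  if (var(l) == 0) {
    # constant input: slope unidentifiable; intercept-only fit maps the
    # constant to the observed prevalence
    return(c(a = qlogis(mean(label)), b = 0))
  }
  fit <- withCallingHandlers(
    glm(label ~ l, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (!fit$converged || any(abs(coef(fit)) > 50)) {
    warnf("separable out-of-fold set; falling back to ridge-penalized fit")
    return(ridge_logistic(l, label))
  }
  c(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]))
}

#' Apply Platt recalibration
#' @param raw Raw probabilities.
#' @param ab Named vector `c(a, b)` from [platt_fit()].
#' @return Recalibrated probabilities.
#' @export
platt_apply <- function(raw, ab) {
  plogis(ab[["a"]] + ab[["b"]] * qlogis(clip_prob(raw)))
}

#' Choose the F-beta-maximizing decision threshold
#'
#' Scans every unique predicted risk as a candidate threshold (alert iff
#' risk >= threshold) and returns the one maximizing the F-beta score;
#' ties break toward the smaller threshold (higher sensitivity).
#'
#' @param risks Predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param beta F-score weight (default 2, sensitivity-prioritized).
#' @return The threshold probability.
#' @export
choose_threshold <- function(risks, labels, beta = 2) {
  if (length(unique(labels)) < 2L)
    stopf("threshold selection needs both classes")
  ord <- order(risks, decreasing = TRUE)
  r <- risks[ord]; y <- labels[ord]
  n1 <- sum(y)
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # candidate thresholds: each unique risk value; alerts = all rows with
  # risk >= that value = the block ending at the last tied position
  last_of_block <- which(!duplicated(r, fromLast = TRUE))
  tp_b <- tp[last_of_block]; fp_b <- fp[last_of_block]
  prec <- tp_b / (tp_b + fp_b)
  rec <- tp_b / n1
  b2 <- beta^2
  f <- (1 + b2) * prec * rec / (b2 * prec + rec)
  f[!is.finite(f)] <- 0
  thr <- r[last_of_block]
  best <- max(f)
  min(thr[f >= best - 1e-12])
}
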