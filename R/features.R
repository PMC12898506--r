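# Window-level trajectory features: summaries over the 12 h feature window,
# long-lookback (48/72 h) OLS slopes, piecewise slope change (PSC), urine
# output, treatment exposure and static descriptors. All features of a
# window use data strictly before its cutoff; trend lookbacks may reach
# further back in time but never forward.

#' Default feature specification
#'
#' One row per engineered feature over the vital-sign and laboratory
#' streams: within-window summaries (12 h mean/sd/min/max/last), 48-72 h
#' slopes and piecewise slope changes for the trajectory-sensitive streams,
#' urine-output totals and weight-normalized rates, vasopressor exposure,
#' and static demographics/comorbidities. `monotone` carries the clinical
#' prior used for constrained boosting: +1 for creatinine, BUN and
#' vasopressor dose, -1 for urine output, 0 otherwise.
#'
#' @return data.table with columns `name`, `source`, `stream`,
#'   `representation`, `lookback`, `monotone`.
#' @export
default_feature_spec <- function() {
  ts <- function(stream, rep, lookback, monotone = 0L, source = "vitals")
    data.table(name = sprintf("%s_%s_%g", stream, rep, lookback),
               source = source, stream = stream, representation = rep,
               lookback = lookback, monotone = as.integer(monotone))
  spec <- rbind(
    ts("map", "mean", 12), ts("map", "sd", 12), ts("map", "min", 12),
    ts("map", "slope", 48), ts("map", "psc", 48),
    ts("hr", "mean", 12), ts("hr", "sd", 12), ts("hr", "max", 12),
    ts("hr", "slope", 48), ts("hr", "psc", 48),
    ts("spo2", "mean", 12), ts("spo2", "min", 12), ts("spo2", "slope", 12),
    ts("spo2", "psc", 48),
    ts("sbp", "mean", 12), ts("sbp", "min", 12),
    ts("dbp", "mean", 12),
    ts("rr", "mean", 12), ts("rr", "max", 12),
    ts("temp", "mean", 12), ts("temp", "slope", 48),
    ts("creatinine", "last", 72, +1L, "labs"),
    ts("creatinine", "slope", 72, +1L, "labs"),
    ts("bun", "last", 72, +1L, "labs"), ts("bun", "slope", 72, +1L, "labs"),
    ts("bicarbonate", "last", 72, 0L, "labs"),
    ts("bicarbonate", "slope", 72, 0L, "labs"),
    ts("anion_gap", "last", 72, 0L, "labs"),
    ts("wbc", "last", 72, 0L, "labs"),
    ts("glucose", "last", 72, 0L, "labs"),
    ts("glucose", "slope", 72, 0L, "labs"),
    ts("hemoglobin", "last", 72, 0L, "labs"),
    ts("platelets", "last", 72, 0L, "labs"),
    ts("sodium", "last", 72, 0L, "labs"),
    ts("potassium", "last", 72, 0L, "labs"),
    ts("chloride", "last", 72, 0L, "labs")
  )
  uo <- data.table(
    name = c("uo_total_12", "uo_rate_12", "uo_rate_6"),
    source = "urine", stream = "uo",
    representation = c("total", "rate", "rate"),
    lookback = c(12, 12, 6), monotone = -1L)
  tr <- data.table(
    name = c("vaso_dose_max_12", "vaso_active_12"),
    source = "treatments", stream = "norepinephrine",
    representation = c("dose_max", "active"),
    lookback = 12, monotone = c(+1L, +1L))
  st <- data.table(
    name = c("age", "weight_last", "ckd", "diabetes", "sepsis", "shock",
             "hypertension", "cirrhosis", "ami", "ahf", "contrast", "covid",
             "sex", "race", "unit_type"),
    source = "static", stream = NA_character_,
    representation = c(rep("numeric", 12), rep("categorical", 3)),
    lookback = NA_real_, monotone = 0L)
  rbind(spec, uo, tr, st)
}

#' Summarize one stream over a window lookback
#'
#' Only points with `time` in `[cutoff - lookback, cutoff)` are visible.
#' `slope` is the OLS slope of value on time (per hour), missing with
#' fewer than 2 points; `sd` missing with fewer than 2 points; `psc`
#' delegates to [piecewise_slope_change()].
#'
#' @param stream data.frame `time`, `value`, sorted by time.
#' @param cutoff Window cutoff (hours).
#' @param representation One of `last`, `mean`, `sd`, `min`, `max`,
#'   `slope`, `psc`.
#' @param lookback Hours of visible history.
#' @return Scalar value, or `NA` when not computable.
#' @export
summarize_window <- function(stream, cutoff, representation, lookback) {
  sel <- stream$time >= cutoff - lookback & stream$time < cutoff
  t <- stream$time[sel]; y <- stream$value[sel]
  n <- length(y)
  switch(representation,
         last = if (n) y[n] else NA_real_,
         mean = if (n) mean(y) else NA_real_,
         sd = if (n >= 2) sd(y) else NA_real_,
         min = if (n) min(y) else NA_real_,
         max = if (n) max(y) else NA_real_,
         slope = ols_slope(t, y),
         psc = piecewise_slope_change(stream, cutoff, lookback),
         stopf("unknown representation '%s'", representation))
}

# Vectorized two-segment continuous fit over all interior candidate
# breakpoints (each observed timestamp with >= 2 points strictly on each
# side). Model: y ~ b0 + b1*t + b2*max(t - bp, 0); PSC = b2. Normal
# equations are solved per candidate by Cramer's rule with suffix sums.
psc_fit <- function(t, y) {
  n <- length(t)
  if (n < 4L) return(NA_real_)
  o <- order(t); t <- t[o]; y <- y[o]
  # candidates: observed timestamps with >= 2 points on each side
  idx <- seq_len(n)
  cand <- idx[idx >= 2L & idx <= n - 2L]
  cand <- cand[t[cand] > t[1] & t[cand] < t[n]]   # interior in time
  if (!length(cand)) return(NA_real_)
  S1 <- sum(t); S2 <- sum(t * t); Sy <- sum(y); Sty <- sum(t * y)
  # suffix sums over points strictly after the breakpoint index
  r_ct <- rev(cumsum(rev(rep(1, n)))); r_t <- rev(cumsum(rev(t)))
  r_t2 <- rev(cumsum(rev(t * t))); r_y <- rev(cumsum(rev(y)))
  r_ty <- rev(cumsum(rev(t * y)))
  suffix <- function(v, j) c(v, 0)[j + 1L]   # sum over indices > j
  best <- c(rss = Inf, psc = NA_real_, bp = NA_real_)
  b <- t[cand]
  j <- cand            # points at indices > j lie strictly after t[cand]? ties:
  # with ties multiple equal t; require strictly greater time
  j <- vapply(cand, function(ci) max(which(t <= t[ci])), integer(1))
  ct <- suffix(r_ct, j); st <- suffix(r_t, j); st2 <- suffix(r_t2, j)
  sy <- suffix(r_y, j); sty <- suffix(r_ty, j)
  Sh <- st - b * ct
  Shh <- st2 - 2 * b * st + b * b * ct
  Sth <- st2 - b * st
  Syh <- sty - b * sy
  # normal equations for (b0, b1, b2):
  # [ n    S1   Sh  ] [b0]   [ Sy  ]
  # [ S1   S2   Sth ] [b1] = [ Sty ]
  # [ Sh   Sth  Shh ] [b2]   [ Syh ]
  det3 <- n * (S2 * Shh - Sth * Sth) - S1 * (S1 * Shh - Sth * Sh) +
    Sh * (S1 * Sth - S2 * Sh)
  ok <- abs(det3) > 1e-9 * max(1, S2)^1.5
  if (!any(ok)) return(NA_real_)
  det_b2 <- n * (S2 * Syh - Sty * Sth) - S1 * (S1 * Syh - Sty * Sh) +
    Sy * (S1 * Sth - S2 * Sh)
  b2 <- det_b2 / det3
  det_b0 <- Sy * (S2 * Shh - Sth * Sth) - S1 * (Sty * Shh - Sth * Syh) +
    Sh * (Sty * Sth - S2 * Syh)
  det_b1 <- n * (Sty * Shh - Syh * Sth) - Sy * (S1 * Shh - Sth * Sh) +
    Sh * (S1 * Syh - Sty * Sh)
  b0 <- det_b0 / det3; b1 <- det_b1 / det3
  # residual sum of squares per candidate
  Syy <- sum(y * y)
  rss <- Syy - (b0 * Sy + b1 * Sty + b2 * Syh)
  rss[!ok] <- Inf
  pick <- which.min(rss)
  b2[pick]
}

#' Piecewise slope change of a trajectory before a cutoff
#'
#' Fits a continuous two-segment linear model with a single breakpoint
#' chosen by least squares over interior candidate timestamps (>= 2 points
#' strictly on each side) and returns the second-segment slope minus the
#' first-segment slope. Missing with fewer than 4 visible points.
#'
#' @param stream data.frame `time`, `value`.
#' @param cutoff Cutoff hour; only `time` in `[cutoff - lookback, cutoff)`
#'   is visible.
#' @param lookback Hours of visible history.
#' @return The slope change (units per hour), or `NA`.
#' @export
piecewise_slope_change <- function(stream, cutoff, lookback) {
  sel <- stream$time >= cutoff - lookback & stream$time < cutoff
  psc_fit(stream$time[sel], stream$value[sel])
}

#' Build the window-level feature matrix
#'
#' @param cohort An `aki_cohort`.
#' @param windows Window table from [build_cohort_windows()].
#' @param spec Feature specification (default [default_feature_spec()]).
#' @return data.table: `window_id`, `patient_id`, `stay_id`, `cutoff`,
#'   `label`, then one column per feature (missing entries `NA`;
#'   categoricals as character). No imputation is performed.
#' @export
build_feature_matrix <- function(cohort, windows, spec = default_feature_spec()) {
  X <- copy(windows)
  ev <- rbind(cohort$vitals[, .(stay_id, stream = variable, time, value)],
              cohort$labs[, .(stay_id, stream = variable, time, value)])
  setkey(ev, stay_id, stream, time)

  ts_spec <- spec[source %in% c("vitals", "labs")]
  smry_spec <- ts_spec[representation != "psc"]
  for (lb in unique(smry_spec$lookback)) {
    streams <- unique(smry_spec[lookback == lb, stream])
    jj <- X[, .(stay_id, window_id, lo = cutoff - lb, hi = cutoff)]
    jj <- jj[rep(seq_len(nrow(jj)), each = length(streams))]
    jj[, stream := rep(streams, times = nrow(jj) / length(streams))]
    agg <- ev[jj, on = .(stay_id, stream, time >= lo, time < hi),
              .(n_pts = sum(!is.na(x.value)),
                mean_v = mean(x.value), sd_v = sd(x.value),
                min_v = suppressWarnings(min(x.value)),
                max_v = suppressWarnings(max(x.value)),
                last_v = x.value[.N],
                slope_v = ols_slope(x.time[!is.na(x.value)],
                                    x.value[!is.na(x.value)])),
              by = .EACHI]
    agg <- cbind(jj[, .(window_id, stream)],
                 agg[, .(n_pts, mean_v, sd_v, min_v, max_v, last_v, slope_v)])
    agg[n_pts == 0, c("mean_v", "min_v", "max_v", "last_v") := NA_real_]
    agg[n_pts < 2, c("sd_v", "slope_v") := NA_real_]
    agg[!is.finite(min_v), min_v := NA_real_]
    agg[!is.finite(max_v), max_v := NA_real_]
    sub <- smry_spec[lookback == lb]
    for (k in seq_len(nrow(sub))) {
      row <- sub[k]
      col <- switch(row$representation,
                    mean = "mean_v", sd = "sd_v", min = "min_v",
                    max = "max_v", last = "last_v", slope = "slope_v")
      vals <- agg[stream == row$stream][X, on = "window_id", get(col)]
      set(X, j = row$name, value = vals)
    }
  }

  psc_spec <- ts_spec[representation == "psc"]
  for (k in seq_len(nrow(psc_spec))) {
    row <- psc_spec[k]
    jj <- X[, .(stay_id, window_id, lo = cutoff - row$lookback, hi = cutoff)]
    jj[, stream := row$stream]
    agg <- ev[jj, on = .(stay_id, stream, time >= lo, time < hi),
              .(psc_v = psc_fit(x.time[!is.na(x.value)],
                                x.value[!is.na(x.value)])),
              by = .EACHI]
    vals <- cbind(jj[, .(window_id)], agg[, .(psc_v)])[X, on = "window_id", psc_v]
    set(X, j = row$name, value = vals)
  }

  # urine output
  uo <- cohort$urine_output
  wt <- cohort$weights[order(stay_id, time)]
  for (lb in unique(spec[source == "urine", lookback])) {
    jj <- X[, .(stay_id, window_id, lo = cutoff - lb, hi = cutoff)]
    s <- uo[jj, on = .(stay_id, time >= lo, time < hi),
            .(tot = sum(volume_ml), n = sum(!is.na(volume_ml))), by = .EACHI]
    tot <- s$tot; tot[s$n == 0] <- NA_real_
    w_at <- wt[X[, .(stay_id, time = cutoff)], on = .(stay_id, time),
               roll = Inf, x.weight_kg]
    for (k in seq_len(nrow(spec[source == "urine" & lookback == lb]))) {
      row <- spec[source == "urine" & lookback == lb][k]
      vals <- if (row$representation == "total") tot else tot / (lb * w_at)
      set(X, j = row$name, value = vals)
    }
  }

  # vasopressor exposure within the feature window
  vaso <- cohort$treatments[drug == "norepinephrine"]
  jj <- X[, .(stay_id, window_id, lo = cutoff - 12, hi = cutoff)]
  if (nrow(vaso)) {
    m <- vaso[jj, on = .(stay_id, start < hi, end > lo),
              .(dmax = suppressWarnings(max(dose)), n = sum(!is.na(dose))),
              by = .EACHI]
    dmax <- m$dmax; dmax[m$n == 0 | !is.finite(dmax)] <- 0
    active <- as.numeric(m$n > 0)
  } else {
    dmax <- numeric(nrow(X)); active <- numeric(nrow(X))
  }
  set(X, j = "vaso_dose_max_12", value = dmax)
  set(X, j = "vaso_active_12", value = active)

  # statics
  st_cols <- c("age", "sex", "race", "unit_type", "ckd", "diabetes", "sepsis",
               "shock", "hypertension", "cirrhosis", "ami", "ahf", "contrast",
               "covid")
  X[cohort$stays, on = "stay_id",
    (st_cols) := mget(paste0("i.", st_cols))]
  w_last <- wt[X[, .(stay_id, time = cutoff)], on = .(stay_id, time),
               roll = Inf, x.weight_kg]
  set(X, j = "weight_last", value = w_last)

  setattr(X, "feature_spec", spec)
  X[]
}

#' One-hot encode categorical feature columns
#'
#' Vocabularies are learned on training rows only; validation levels unseen
#' in training map to all-zero indicators. Binary 0/1 columns pass through.
#'
#' @param X Feature matrix (data.table).
#' @param cat_cols Character columns to encode (default: all character
#'   feature columns).
#' @param train_mask Logical vector marking training rows.
#' @param vocab Optional prelearned vocabulary (named list of levels) to
#'   reapply; when supplied, `train_mask` is ignored.
#' @return List `X` (encoded copy) and `vocab`.
#' @export
encode_categoricals <- function(X, cat_cols = NULL, train_mask = NULL,
                                vocab = NULL) {
  X <- copy(X)
  if (is.null(cat_cols))
    cat_cols <- names(X)[vapply(X, is.character, logical(1))]
  cat_cols <- setdiff(cat_cols, c("window_id", "patient_id", "stay_id"))
  if (is.null(vocab)) {
    if (is.null(train_mask)) train_mask <- rep(TRUE, nrow(X))
    vocab <- lapply(cat_cols, function(cc)
      sort(unique(X[[cc]][train_mask & !is.na(X[[cc]])])))
    names(vocab) <- cat_cols
  }
  for (cc in names(vocab)) {
    for (lev in vocab[[cc]]) {
      set(X, j = paste0(cc, "_", lev),
          value = as.numeric(!is.na(X[[cc]]) & X[[cc]] == lev))
    }
    set(X, j = cc, value = NULL)
  }
  list(X = X, vocab = vocab)
}

#' Screen features on training rows
#'
#' Drops columns with more than 50% missingness on training rows and
#' near-zero-variance columns (most frequent non-missing value covering
#' more than 99% of training rows, or fewer than two distinct values).
#' Collinear pairs (|Pearson| or |Spearman| > 0.95 on pairwise-complete
#' training rows) are reported but never dropped automatically. The
#' retained set must be applied unchanged to validation frames.
#'
#' @param X Encoded feature matrix.
#' @param feature_cols Candidate feature column names.
#' @param train_mask Logical vector marking training rows.
#' @param missing_max Maximum training missing fraction (default 0.5).
#' @param nzv_share Near-zero-variance dominant-share threshold (0.99).
#' @param cor_thresh Collinearity report threshold (0.95).
#' @return List `retained`, `report` (per-column diagnostics),
#'   `collinearity` (flagged pairs).
#' @export
screen_features <- function(X, feature_cols, train_mask,
                            missing_max = 0.5, nzv_share = 0.99,
                            cor_thresh = 0.95) {
  if (!any(train_mask)) stopf("empty training mask")
  Xt <- X[train_mask]
  n <- nrow(Xt)
  rep_l <- lapply(feature_cols, function(fc) {
    v <- Xt[[fc]]
    miss <- mean(is.na(v))
    vv <- v[!is.na(v)]
    share <- if (length(vv)) max(tabulate(as.integer(factor(vv)))) / n else 1
    nzv <- share > nzv_share || length(unique(vv)) < 2L
    data.table(feature = fc, missing_frac = miss, dominant_share = share,
               nzv = nzv,
               dropped = miss > missing_max || nzv,
               reason = if (miss > missing_max) "missingness"
               else if (nzv) "near_zero_variance" else NA_character_)
  })
  report <- rbindlist(rep_l)
  retained <- report[dropped == FALSE, feature]

  coll <- data.table(f1 = character(), f2 = character(),
                     pearson = numeric(), spearman = numeric())
  if (length(retained) >= 2) {
    M <- as.matrix(Xt[, ..retained])
    suppressWarnings({
      cp <- cor(M, use = "pairwise.complete.obs", method = "pearson")
      cs <- cor(M, use = "pairwise.complete.obs", method = "spearman")
    })
    hit <- which((abs(cp) > cor_thresh | abs(cs) > cor_thresh) &
                   upper.tri(cp), arr.ind = TRUE)
    if (nrow(hit)) {
      coll <- data.table(f1 = retained[hit[, 1]], f2 = retained[hit[, 2]],
                         pearson = cp[hit], spearman = cs[hit])
    }
  }
  list(retained = retained, report = report, collinearity = coll)
}
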