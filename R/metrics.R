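# Discrimination, calibration, decision-curve, subgroup and balance
# statistics, with patient-clustered bootstrap confidence intervals.

#' Threshold-based classification metrics
#'
#' Alerts are issued when `risk >= pt` (closed on the left). Undefined
#' metrics (e.g. precision with zero alerts, or any class-dependent metric
#' with single-class labels) are returned as `NA` and flagged, never
#' silently zero.
#'
#' @param risks Predicted probabilities in `[0, 1]`.
#' @param labels 0/1 outcomes.
#' @param pt Threshold probability.
#' @return List with `tp`, `fp`, `tn`, `fn`, `recall`, `specificity`,
#'   `precision`, `f1`, `f2`, `balanced_accuracy`, `mcc`, `brier`,
#'   `undefined` (character vector of flagged metrics).
#' @export
confusion_metrics <- function(risks, labels, pt) {
  if (any(risks < 0 | risks > 1, na.rm = TRUE)) stopf("risks must lie in [0, 1]")
  alert <- risks >= pt
  tp <- sum(alert & labels == 1); fp <- sum(alert & labels == 0)
  fn <- sum(!alert & labels == 1); tn <- sum(!alert & labels == 0)
  undef <- character()
  div <- function(num, den, nm) {
    if (den == 0) { undef <<- c(undef, nm); NA_real_ } else num / den
  }
  recall <- div(tp, tp + fn, "recall")
  specificity <- div(tn, tn + fp, "specificity")
  precision <- div(tp, tp + fp, "precision")
  fbeta <- function(beta, nm) {
    if (is.na(precision) || is.na(recall)) {
      undef <<- c(undef, nm)
      return(NA_real_)
    }
    if (precision + recall == 0) return(0)
    (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
  }
  f1 <- fbeta(1, "f1"); f2 <- fbeta(2, "f2")
  balanced_accuracy <- if (is.na(recall) || is.na(specificity)) {
    undef <- c(undef, "balanced_accuracy"); NA_real_
  } else (recall + specificity) / 2
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) { undef <- c(undef, "mcc"); NA_real_ } else
    (tp * tn - fp * fn) / mcc_den
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       recall = recall, specificity = specificity, precision = precision,
       f1 = f1, f2 = f2, balanced_accuracy = balanced_accuracy, mcc = mcc,
       brier = mean((risks - labels)^2), undefined = unique(undef))
}

#' Rank-based discrimination metrics
#'
#' AUC is the tie-corrected Mann-Whitney probability; AUPRC integrates the
#' precision-recall curve with step interpolation over distinct score
#' values.
#'
#' @param risks Predicted scores.
#' @param labels 0/1 outcomes (both classes required).
#' @return List `auc`, `auprc`.
#' @export
rank_metrics <- function(risks, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes required for rank metrics")
  r <- rank(risks)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(risks, decreasing = TRUE)
  y <- labels[ord]; s <- risks[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  block <- which(!duplicated(s, fromLast = TRUE))
  prec <- tp[block] / (tp[block] + fp[block])
  rec <- tp[block] / n1
  drec <- diff(c(0, rec))
  auprc <- sum(drec * prec)
  list(auc = auc, auprc = auprc)
}

#' Patient-clustered percentile bootstrap confidence interval
#'
#' Resamples clusters (patients) with replacement, recomputes the statistic
#' on each replicate, and returns percentile bounds. Replicates on which
#' the statistic is undefined (`NA` or error) are excluded and counted.
#'
#' @param statistic Function `data.frame -> scalar`.
#' @param data data.frame/data.table of rows.
#' @param cluster_ids Cluster label per row.
#' @param B Number of replicates (default 2000).
#' @param seed Seed.
#' @param conf Coverage (default 0.95).
#' @return List `est`, `lower`, `upper`, `B`, `n_dropped`, `degenerate`
#'   (TRUE when only one cluster exists).
#' @export
cluster_bootstrap <- function(statistic, data, cluster_ids, B = 2000L,
                              seed = 1L, conf = 0.95) {
  if (B < 1) stopf("B must be >= 1")
  data <- as.data.table(data)
  est <- statistic(data)
  idx_by <- split(seq_len(nrow(data)), cluster_ids)
  n_cl <- length(idx_by)
  set.seed(seed)
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    cl <- sample.int(n_cl, n_cl, replace = TRUE)
    rows <- unlist(idx_by[cl], use.names = FALSE)
    reps[b] <- tryCatch(statistic(data[rows]), error = function(e) NA_real_)
  }
  ok <- !is.na(reps)
  alpha <- (1 - conf) / 2
  qs <- if (any(ok)) quantile(reps[ok], c(alpha, 1 - alpha), names = FALSE,
                              type = 7) else c(NA_real_, NA_real_)
  list(est = est, lower = qs[1], upper = qs[2], B = B,
       n_dropped = sum(!ok), degenerate = n_cl == 1L)
}

#' Calibration diagnostics
#'
#' Calibration slope and intercept come from a logistic regression of the
#' label on the logit of predicted risk; calibration-in-the-large (CITL) is
#' the intercept of the same model with the slope fixed at 1 (offset
#' model). ECE uses equal-width bins on `[0, 1]`.
#'
#' @param risks Predicted probabilities (values of exactly 0/1 are clipped
#'   with a warning).
#' @param labels 0/1 outcomes.
#' @param n_bins Number of equal-width reliability bins (default 10).
#' @return List `intercept`, `slope`, `citl`, `ece`, `brier`,
#'   `reliability` (data.table `bin`, `mean_risk`, `event_rate`, `n`).
#' @export
calibration_suite <- function(risks, labels, n_bins = 10L) {
  if (length(unique(labels)) < 2L) stopf("both classes required")
  if (any(risks <= 0 | risks >= 1)) {
    warnf("risks of exactly 0/1 clipped to [1e-6, 1 - 1e-6]")
  }
  p <- clip_prob(risks)
  l <- qlogis(p)
  fit <- suppressWarnings(glm(labels ~ l, family = binomial()))
  off <- suppressWarnings(glm(labels ~ 1 + offset(l), family = binomial()))
  bins <- cut(p, breaks = seq(0, 1, length.out = n_bins + 1),
              include.lowest = TRUE, labels = FALSE)
  rel <- data.table(bin = bins, p = p, y = labels)[
    , .(mean_risk = mean(p), event_rate = mean(y), n = .N), by = bin][order(bin)]
  ece <- rel[, sum(n / length(p) * abs(mean_risk - event_rate))]
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       citl = unname(coef(off)[1]), ece = ece,
       brier = mean((risks - labels)^2), reliability = rel[])
}

#' Net benefit of a risk model at a threshold probability
#'
#' `NB = TP/N - (FP/N) * pt / (1 - pt)`: true positives minus false
#' positives weighted by the threshold-derived harm/benefit trade-off.
#'
#' @param risks Predicted probabilities; alert iff `risk >= pt`.
#' @param labels 0/1 outcomes.
#' @param pt Threshold probability in (0, 1).
#' @return Net benefit (per window).
#' @export
net_benefit <- function(risks, labels, pt) {
  if (pt <= 0 || pt >= 1) stopf("pt must lie in (0, 1)")
  n <- length(labels)
  alert <- risks >= pt
  tp <- sum(alert & labels == 1); fp <- sum(alert & labels == 0)
  tp / n - (fp / n) * pt / (1 - pt)
}

#' Net benefit of the treat-all policy
#'
#' `NB_all = pi - (1 - pi) * pt / (1 - pt)` for prevalence `pi`.
#'
#' @param prevalence Event prevalence in `[0, 1]`.
#' @param pt Threshold probability in (0, 1).
#' @return Net benefit of treating every window.
#' @export
nb_treat_all <- function(prevalence, pt) {
  if (pt <= 0 || pt >= 1) stopf("pt must lie in (0, 1)")
  prevalence - (1 - prevalence) * pt / (1 - pt)
}

#' Decision curve
#'
#' Net benefit of the model, treat-all and treat-none policies over a grid
#' of threshold probabilities, plus avoided unnecessary interventions per
#' 100 windows relative to treat-all.
#'
#' @param risks Predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param pt_grid Threshold grid (default 0.01-0.5).
#' @return data.table `pt`, `nb_model`, `nb_all`, `nb_none`,
#'   `avoided_per_100`.
#' @export
dca_curve <- function(risks, labels, pt_grid = seq(0.01, 0.5, by = 0.01)) {
  prev <- mean(labels)
  rows <- lapply(pt_grid, function(pt) {
    w <- pt / (1 - pt)
    nbm <- net_benefit(risks, labels, pt)
    nba <- nb_treat_all(prev, pt)
    data.table(pt = pt, nb_model = nbm, nb_all = nba, nb_none = 0,
               avoided_per_100 = 100 * (nbm - nba) / w)
  })
  rbindlist(rows)
}

# Midrank placements for the DeLong AUC variance.
delong_placements <- function(risks, labels) {
  x <- risks[labels == 1]; y <- risks[labels == 0]
  m <- length(x); n <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_x) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_y) / m
  auc <- sum(v10) / m
  list(auc = auc, v10 = v10, v01 = v01)
}

#' Unpaired DeLong comparison of two AUCs
#'
#' AUC variance per group via placement values; two-sided normal test on
#' the AUC difference; Bonferroni correction across `m_comparisons`.
#'
#' @param risks_g1,labels_g1 Scores and outcomes for group 1.
#' @param risks_g2,labels_g2 Scores and outcomes for group 2.
#' @param m_comparisons Number of comparisons in the family (default 1).
#' @return List `auc1`, `auc2`, `var1`, `var2`, `z`, `p`, `p_bonferroni`.
#' @export
delong_compare <- function(risks_g1, labels_g1, risks_g2, labels_g2,
                           m_comparisons = 1L) {
  for (lab in list(labels_g1, labels_g2))
    if (length(unique(lab)) < 2L) stopf("each group needs both classes")
  p1 <- delong_placements(risks_g1, labels_g1)
  p2 <- delong_placements(risks_g2, labels_g2)
  v1 <- var(p1$v10) / length(p1$v10) + var(p1$v01) / length(p1$v01)
  v2 <- var(p2$v10) / length(p2$v10) + var(p2$v01) / length(p2$v01)
  se <- sqrt(v1 + v2)
  d <- p1$auc - p2$auc
  z <- if (se == 0) { if (d == 0) 0 else sign(d) * Inf } else d / se
  p <- 2 * pnorm(-abs(z))
  list(auc1 = p1$auc, auc2 = p2$auc, var1 = v1, var2 = v2, z = z, p = p,
       p_bonferroni = min(1, m_comparisons * p))
}

#' Absolute standardized mean difference between two cohorts
#'
#' Continuous: `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)`; binary (detected as
#' values in {0, 1}): `|p1 - p2| / sqrt((p1(1-p1) + p2(1-p2)) / 2)`.
#' Computed over non-missing windows with optional per-window weights.
#'
#' @param values_dev,values_other Variable values in the two cohorts.
#' @param weights_dev,weights_other Optional window weights (default 1).
#' @return The ASMD (possibly `Inf` when the pooled SD is zero with
#'   unequal means, flagged with a warning).
#' @export
asmd <- function(values_dev, values_other,
                 weights_dev = NULL, weights_other = NULL) {
  prep <- function(v, w) {
    if (is.null(w)) w <- rep(1, length(v))
    keep <- !is.na(v)
    list(v = v[keep], w = w[keep])
  }
  a <- prep(values_dev, weights_dev); b <- prep(values_other, weights_other)
  wmean <- function(z) sum(z$w * z$v) / sum(z$w)
  wvar <- function(z) {
    m <- wmean(z)
    sum(z$w * (z$v - m)^2) / sum(z$w)
  }
  vals <- c(a$v, b$v)
  binary <- all(vals %in% c(0, 1))
  m1 <- wmean(a); m2 <- wmean(b)
  pooled <- if (binary) (m1 * (1 - m1) + m2 * (1 - m2)) / 2 else
    (wvar(a) + wvar(b)) / 2
  if (pooled == 0) {
    if (abs(m1 - m2) < .Machine$double.eps^0.5) return(0)
    warnf("zero pooled SD with unequal means; ASMD is infinite")
    return(Inf)
  }
  abs(m1 - m2) / sqrt(pooled)
}

#' Full discrimination report with clustered bootstrap CIs
#'
#' Point estimates and percentile bootstrap CIs (clustered at the patient
#' level) for AUC, AUPRC, the threshold metrics at `pt`, and the Brier
#' score.
#'
#' @param risks Predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param cluster_ids Patient identifier per row.
#' @param pt Operating threshold.
#' @param B Bootstrap replicates (default 2000).
#' @param seed Seed.
#' @return data.table `metric`, `estimate`, `lower`, `upper`.
#' @export
metrics_report <- function(risks, labels, cluster_ids, pt, B = 2000L,
                           seed = 1L) {
  dat <- data.table(risk = risks, label = labels)
  stat_all <- function(df) {
    rm_ <- tryCatch(rank_metrics(df$risk, df$label),
                    error = function(e) list(auc = NA_real_, auprc = NA_real_))
    cm <- confusion_metrics(df$risk, df$label, pt)
    c(auc = rm_$auc, auprc = rm_$auprc, recall = cm$recall,
      specificity = cm$specificity, precision = cm$precision, f1 = cm$f1,
      f2 = cm$f2, balanced_accuracy = cm$balanced_accuracy, mcc = cm$mcc,
      brier = cm$brier)
  }
  est <- stat_all(dat)
  idx_by <- split(seq_len(nrow(dat)), cluster_ids)
  n_cl <- length(idx_by)
  set.seed(seed)
  reps <- matrix(NA_real_, nrow = B, ncol = length(est),
                 dimnames = list(NULL, names(est)))
  for (b in seq_len(B)) {
    cl <- sample.int(n_cl, n_cl, replace = TRUE)
    rows <- unlist(idx_by[cl], use.names = FALSE)
    reps[b, ] <- stat_all(dat[rows])
  }
  qs <- apply(reps, 2, function(col)
    quantile(col, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
  data.table(metric = names(est), estimate = unname(est),
             lower = qs[1, ], upper = qs[2, ])
}
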