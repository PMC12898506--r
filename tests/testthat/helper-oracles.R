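# Independent brute-force oracles and shared fixtures. These deliberately
# avoid the package's vectorized code paths: plain loops and closed forms.

library(data.table)

# Mann-Whitney AUC by exhaustive pair counting.
oracle_auc <- function(risks, labels) {
  x <- risks[labels == 1]; y <- risks[labels == 0]
  s <- 0
  for (xi in x) s <- s + sum(xi > y) + 0.5 * sum(xi == y)
  s / (length(x) * length(y))
}

# Two-segment continuous least-squares fit via lm() over every interior
# candidate breakpoint; returns slope2 - slope1 of the best fit.
oracle_psc <- function(t, y) {
  n <- length(t)
  if (n < 4) return(NA_real_)
  o <- order(t); t <- t[o]; y <- y[o]
  cand <- t[seq(2, n - 2)]
  cand <- cand[cand > t[1] & cand < t[n]]
  best <- NULL; best_rss <- Inf
  for (b in cand) {
    h <- pmax(t - b, 0)
    fit <- lm(y ~ t + h)
    rss <- sum(residuals(fit)^2)
    if (rss < best_rss - 1e-12) { best_rss <- rss; best <- fit }
  }
  if (is.null(best)) return(NA_real_)
  unname(coef(best)[["h"]])
}

# Window labels by brute-force double loop over (window, onset).
oracle_window_labels <- function(windows, onsets, scheme) {
  lab <- integer(nrow(windows))
  for (i in seq_len(nrow(windows))) {
    on <- onsets$onset[match(windows$stay_id[i], onsets$stay_id)]
    lo <- windows$cutoff[i] + scheme$gap
    lab[i] <- as.integer(!is.na(on) && on >= lo && on < lo + scheme$horizon)
  }
  lab
}

# DeLong placement values by explicit double loops.
oracle_placements <- function(risks, labels) {
  x <- risks[labels == 1]; y <- risks[labels == 0]
  psi <- function(a, b) if (a > b) 1 else if (a == b) 0.5 else 0
  v10 <- vapply(x, function(xi) mean(vapply(y, function(yj) psi(xi, yj),
                                            numeric(1))), numeric(1))
  v01 <- vapply(y, function(yj) mean(vapply(x, function(xi) psi(xi, yj),
                                            numeric(1))), numeric(1))
  list(auc = mean(v10), v10 = v10, v01 = v01)
}

# Per-stay alert enumeration: categories, first-alert leads, burden.
oracle_alert_enum <- function(windows, risks, pt, onsets, stays, scheme) {
  cov_len <- scheme$gap + scheme$horizon
  res <- list()
  for (i in seq_len(nrow(windows))) {
    if (risks[i] < pt) next
    sid <- windows$stay_id[i]; cut <- windows$cutoff[i]
    on <- onsets$onset[match(sid, onsets$stay_id)]
    cat_ <- if (is.na(on)) "fp_no_aki"
    else if (on - cut <= cov_len) "tp_within_horizon"
    else if (on - cut <= 48) "fp_24_48"
    else if (on - cut <= 72) "fp_48_72"
    else "fp_gt72"
    res[[length(res) + 1]] <- data.table(stay_id = sid, cutoff = cut,
                                         onset = on, category = cat_)
  }
  alerts <- if (length(res)) rbindlist(res) else
    data.table(stay_id = character(), cutoff = numeric(), onset = numeric(),
               category = character())
  ev_stays <- onsets$stay_id[!is.na(onsets$onset)]
  leads <- c()
  for (sid in ev_stays) {
    tp <- alerts[stay_id == sid & category == "tp_within_horizon"]
    if (nrow(tp)) {
      on <- onsets$onset[match(sid, onsets$stay_id)]
      leads <- c(leads, on - min(tp$cutoff))
    }
  }
  det <- function(h) if (length(ev_stays) == 0) 0 else sum(leads > h) / length(ev_stays)
  # burden by per-stay interval union
  union_hours <- function(iv, cap = Inf) {
    if (!nrow(iv)) return(0)
    iv$e <- pmin(iv$e, cap); iv <- iv[iv$e > iv$s, ]
    if (!nrow(iv)) return(0)
    iv <- iv[order(iv$s), ]
    tot <- 0; cs <- iv$s[1]; ce <- iv$e[1]
    for (j in seq_len(nrow(iv))[-1]) {
      if (iv$s[j] <= ce) ce <- max(ce, iv$e[j])
      else { tot <- tot + ce - cs; cs <- iv$s[j]; ce <- iv$e[j] }
    }
    tot + ce - cs
  }
  raw <- 0; capped <- 0; n_rep <- 0; n_any <- 0; n_ge2 <- 0
  for (sid in stays$stay_id) {
    a <- alerts[stay_id == sid][order(cutoff)]
    if (nrow(a) >= 1) n_any <- n_any + 1
    if (nrow(a) >= 2) n_ge2 <- n_ge2 + 1
    if (!nrow(a)) next
    dis <- stays$discharge_time[match(sid, stays$stay_id)]
    iv <- data.frame(s = a$cutoff, e = a$cutoff + cov_len)
    raw <- raw + union_hours(iv)
    capped <- capped + union_hours(iv, cap = dis)
    for (j in seq_len(nrow(a))[-1])
      if (a$cutoff[j] < max(a$cutoff[seq_len(j - 1)] + cov_len)) n_rep <- n_rep + 1
  }
  list(alerts = alerts, detection = vapply(c(6, 12, 18, 24), det, numeric(1)),
       n_events = length(ev_stays),
       total = nrow(alerts),
       per_day = nrow(alerts) / (sum(stays$discharge_time) / 24),
       raw = raw, capped = capped, n_repeat = n_rep,
       frac_any = n_any / nrow(stays), frac_ge2 = n_ge2 / nrow(stays))
}

# Shared small cohort (cached across test files).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_patients = 50, seed = 404)
      cache <<- list(cohort = simulate_cohort(cfg), config = cfg)
    }
    cache
  }
})

# Scalar per-stay stream accessor mirroring the labeler's inputs.
stay_for <- function(cohort, sid) {
  list(
    scr = as.data.frame(cohort$labs[stay_id == sid & variable == "creatinine",
                                    .(time, value)][order(time)]),
    uo = as.data.frame(cohort$urine_output[stay_id == sid,
                                           .(time, volume_ml)][order(time)]),
    weights = as.data.frame(cohort$weights[stay_id == sid,
                                           .(time, weight_kg)][order(time)]),
    rrt = as.data.frame(cohort$rrt[stay_id == sid, .(start, end)][order(start)]),
    discharge_time = cohort$stays[stay_id == sid, discharge_time]
  )
}

# Exact confusion populations realizing printed precision/recall/specificity
# (counts scaled to integers so the ratios are exact).
confusion_vectors <- function(tp, fp, fn, tn) {
  list(risks = c(rep(1, tp + fp), rep(0, fn + tn)),
       labels = c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn)))
}

# A hand-enumerable 20-stay alert fixture: known onsets, crafted risks.
make_alert_fixture <- function() {
  set.seed(55)
  stays <- data.table(
    stay_id = sprintf("A%02d", 1:20),
    discharge_time = c(40, 96, 96, 120, 60, 48, 200, 96, 72, 96,
                       30, 96, 150, 96, 96, 64, 96, 96, 96, 96))
  onsets <- data.table(
    stay_id = stays$stay_id,
    onset = c(NA, 30, 70, 100, NA, 20, 150, NA, 40, 28,
              NA, NA, 80, 44, NA, 50, NA, 26, NA, 90))
  sch <- window_scheme()
  windows <- build_cohort_windows(
    cbind(stays, data.table(patient_id = stays$stay_id)), onsets, sch)
  risks <- ifelse((seq_len(nrow(windows)) %% 3) == 0, 0.9, 0.01)
  risks[windows$stay_id == "A02" & windows$cutoff %in% c(12, 18)] <- 0.9
  risks[windows$stay_id == "A03" & windows$cutoff == 12] <- 0.9
  risks[windows$stay_id == "A01"] <- 0.01
  risks[windows$stay_id == "A01" & windows$cutoff == 12] <- 0.9
  list(stays = stays, onsets = onsets, windows = windows, risks = risks,
       scheme = sch)
}

strong_effects <- c(map_downtrend = 2.5, low_uo = 2.5, sepsis_flag = 2,
                    ckd_flag = 2, age = 0.8)
null_effects <- c(map_downtrend = 0, low_uo = 0, sepsis_flag = 0,
                  ckd_flag = 0, age = 0)
accept_grid <- list(list(max_depth = 4, eta = 0.05, subsample = 0.8,
                         colsample_bytree = 0.8, min_child_weight = 10))
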