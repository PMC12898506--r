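# Time-respecting KDIGO staging and AKI onset detection.
#
# Creatinine criteria use a time-varying baseline computed strictly before
# the assessment time: the minimum serum creatinine (SCr) in the preceding
# 48 h (for the >= 0.3 mg/dL absolute-rise criterion) and in the preceding
# 7 days (for the 1.5x/2x/3x relative-rise criteria). Urine-output criteria
# use rolling 6/12/24 h rates normalized to the most recent body weight.
# RRT initiation forces stage 3. Stage bands are half-open: ratio in
# [1.5, 2) -> 1, [2, 3) -> 2, [3, Inf) -> 3; urine thresholds are strict.
# The SCr >= 4.0 mg/dL absolute stage-3 rule is deliberately not applied:
# staging is built from the rise/ratio/RRT criteria only.

#' Time-varying serum creatinine baselines at time t
#'
#' Only measurements strictly before `t` contribute; the 48 h and 7 day
#' lookbacks are half-open intervals `(t - W, t)`. A baseline is missing
#' when its lookback contains no prior measurement.
#'
#' @param scr_series data.frame with columns `time` (hours) and `value`
#'   (mg/dL), sorted by time.
#' @param t Assessment time in hours (>= 0).
#' @return List with `t`, `min48`, `min7d` (either may be `NA`).
#' @export
baseline_scr <- function(scr_series, t) {
  tt <- scr_series$time
  if (is.unsorted(tt)) stopf("scr_series must be sorted by time")
  if (any(scr_series$value <= 0, na.rm = TRUE)) stopf("creatinine must be > 0")
  in48 <- tt > t - 48 & tt < t
  in7d <- tt > t - 168 & tt < t
  list(t = t,
       min48 = if (any(in48)) min(scr_series$value[in48]) else NA_real_,
       min7d = if (any(in7d)) min(scr_series$value[in7d]) else NA_real_)
}

#' Creatinine-based KDIGO stage
#'
#' Stage 1 if the rise over the 48 h minimum is >= 0.3 mg/dL or the ratio to
#' the 7 day minimum lies in `[1.5, 2)`; stage 2 for ratio in `[2, 3)`;
#' stage 3 for ratio >= 3. The highest satisfied stage wins. Returns `NA`
#' (not computable) when both baselines are missing.
#'
#' @param scr_value Current SCr (mg/dL, > 0).
#' @param baselines Result of [baseline_scr()].
#' @return Integer stage 0-3, or `NA` when not computable.
#' @export
stage_creatinine <- function(scr_value, baselines) {
  if (is.na(scr_value)) return(NA_integer_)
  if (scr_value <= 0) stopf("creatinine must be > 0")
  m48 <- baselines$min48; m7 <- baselines$min7d
  if (is.na(m48) && is.na(m7)) return(NA_integer_)
  stage <- 0L
  if (!is.na(m48) && scr_value - m48 >= 0.3) stage <- max(stage, 1L)
  if (!is.na(m7)) {
    r <- scr_value / m7
    if (r >= 3)   stage <- max(stage, 3L)
    else if (r >= 2) stage <- max(stage, 2L)
    else if (r >= 1.5) stage <- max(stage, 1L)
  }
  stage
}

#' Rolling weight-normalized urine-output rates at time t
#'
#' `rateW` is the charted urine volume in the half-open window `[t - W, t)`
#' divided by `W * weight`, with weight the most recent record at or before
#' `t`. All rates are missing when no weight is available; a rate is missing
#' when its window contains no charted urine event (absence of charting is
#' indistinguishable from absence of output) or when the full lookback does
#' not fit inside the stay (`t < W`; the time axis starts at admission).
#'
#' @param uo_events data.frame with `time` (hours) and `volume_ml`, sorted.
#' @param weight_records data.frame with `time` and `weight_kg`, sorted.
#' @param t Assessment time (hours).
#' @return List with `t`, `rate6`, `rate12`, `rate24` (mL/kg/h) and
#'   `weight_used` (kg), any of which may be `NA`.
#' @export
uo_rates <- function(uo_events, weight_records, t) {
  if (nrow(uo_events) && is.unsorted(uo_events$time))
    stopf("uo_events must be sorted by time")
  if (any(uo_events$volume_ml < 0, na.rm = TRUE)) stopf("urine volumes must be >= 0")
  w <- NA_real_
  if (nrow(weight_records)) {
    prior <- weight_records$time <= t
    if (any(prior)) w <- weight_records$weight_kg[max(which(prior))]
  }
  rate <- function(W) {
    # a rate needs a full lookback window inside the stay (time axis starts
    # at admission, t = 0) and at least one charted event in it
    if (is.na(w) || t < W) return(NA_real_)
    sel <- uo_events$time >= t - W & uo_events$time < t
    if (!any(sel)) return(NA_real_)
    sum(uo_events$volume_ml[sel]) / (W * w)
  }
  list(t = t, rate6 = rate(6), rate12 = rate(12), rate24 = rate(24),
       weight_used = w)
}

#' Urine-output-based KDIGO stage
#'
#' Stage 1 if `rate6 < 0.5`; stage 2 if `rate12 < 0.5`; stage 3 if
#' `rate24 < 0.3` or `rate12 == 0` (anuria). Thresholds are strict; the
#' highest satisfied stage wins. `NA` when all rates are missing.
#'
#' @param rates Result of [uo_rates()].
#' @return Integer stage 0-3, or `NA` when not computable.
#' @export
stage_urine <- function(rates) {
  r6 <- rates$rate6; r12 <- rates$rate12; r24 <- rates$rate24
  if (is.na(r6) && is.na(r12) && is.na(r24)) return(NA_integer_)
  stage <- 0L
  if (!is.na(r6) && r6 < 0.5) stage <- max(stage, 1L)
  if (!is.na(r12) && r12 < 0.5) stage <- max(stage, 2L)
  if ((!is.na(r24) && r24 < 0.3) || (!is.na(r12) && r12 == 0)) stage <- 3L
  stage
}

# Extract the per-stay event streams a KDIGO assessment needs.
stay_streams <- function(cohort, sid) {
  labs <- cohort$labs[stay_id == sid & variable == "creatinine",
                      .(time, value)][order(time)]
  list(
    scr = labs,
    uo = cohort$urine_output[stay_id == sid, .(time, volume_ml)][order(time)],
    weights = cohort$weights[stay_id == sid, .(time, weight_kg)][order(time)],
    rrt = cohort$rrt[stay_id == sid, .(start, end)][order(start)],
    discharge_time = cohort$stays[stay_id == sid, discharge_time]
  )
}

#' KDIGO assessment of a single stay at time t
#'
#' The current SCr is the most recent measurement at or before `t`;
#' baselines use strictly prior measurements. The overall stage is the
#' maximum of the computable component stages (not-computable components
#' count as 0), with stage 3 whenever an RRT episode has started at or
#' before `t`.
#'
#' @param stay List with elements `scr`, `uo`, `weights`, `rrt` as returned
#'   by the internal accessors (data.frames as in [baseline_scr()] /
#'   [uo_rates()]; `rrt` has `start`, `end`).
#' @param t Assessment time (hours).
#' @return List with `t`, `cr_stage`, `uo_stage`, `rrt_stage`,
#'   `overall_stage`.
#' @export
assess_kdigo <- function(stay, t) {
  cur <- NA_real_
  if (nrow(stay$scr)) {
    prior <- stay$scr$time <= t
    if (any(prior)) cur <- stay$scr$value[max(which(prior))]
  }
  cr <- if (is.na(cur)) NA_integer_ else
    stage_creatinine(cur, baseline_scr(stay$scr, t))
  uo <- stage_urine(uo_rates(stay$uo, stay$weights, t))
  rrt <- if (nrow(stay$rrt) && any(stay$rrt$start <= t)) 3L else 0L
  overall <- max(c(0L, cr, uo, rrt), na.rm = TRUE)
  list(t = t, cr_stage = cr, uo_stage = uo, rrt_stage = rrt,
       overall_stage = overall)
}

# Assessment grid for one stay: every creatinine timestamp, an hourly grid,
# and RRT episode starts (so RRT-driven onsets land exactly on the start).
assessment_times <- function(stay) {
  grid <- seq(1, max(1, floor(stay$discharge_time)), by = 1)
  sort(unique(c(stay$scr$time, grid, stay$rrt$start)))
}

#' AKI onset time of a single stay
#'
#' Earliest assessment time with overall KDIGO stage >= 1, or `NA` if no
#' criterion is ever met before discharge.
#'
#' @param stay Stay streams (see [assess_kdigo()]).
#' @param times Assessment times; defaults to the union of creatinine
#'   timestamps, an hourly grid and RRT starts.
#' @return Onset time in hours, or `NA`.
#' @export
aki_onset <- function(stay, times = assessment_times(stay)) {
  for (t in times) {
    if (assess_kdigo(stay, t)$overall_stage >= 1L) return(t)
  }
  NA_real_
}

#' Vectorized KDIGO assessment of a whole cohort
#'
#' Evaluates every KDIGO criterion for every stay at the union of
#' creatinine timestamps, an hourly grid and RRT starts, using
#' data.table non-equi joins. Equivalent to calling [assess_kdigo()] at
#' every assessment time (the test suite asserts exact agreement).
#'
#' @param cohort An `aki_cohort` (or any list of tables with the same schema).
#' @param criteria `"full"` (default), `"creatinine_only"` or `"uo_only"`;
#'   restricted variants keep the RRT criterion and drop the other stream,
#'   supporting label-definition sensitivity analyses.
#' @return data.table with `stay_id`, `t`, `cr_stage`, `uo_stage`,
#'   `rrt_stage`, `overall_stage` (component stages `NA` = not computable).
#' @export
assess_cohort <- function(cohort, criteria = c("full", "creatinine_only", "uo_only")) {
  criteria <- match.arg(criteria)
  stays <- cohort$stays
  scr <- cohort$labs[variable == "creatinine", .(stay_id, time, value)]
  setkey(scr, stay_id, time)

  grid <- stays[, .(t_ = seq(1, max(1, floor(discharge_time)), by = 1)),
                by = stay_id]
  tms <- rbind(grid,
               scr[, .(stay_id, t_ = time)],
               cohort$rrt[, .(stay_id, t_ = start)])
  tms <- unique(tms)[order(stay_id, t_)]

  # current SCr: most recent measurement at or before t
  cur <- data.table(stay_id = tms$stay_id, t_ = tms$t_,
                    cur_scr = scr[tms, on = .(stay_id, time = t_),
                                  roll = Inf, x.value])

  j48 <- tms[, .(stay_id, t_, lo = t_ - 48, hi = t_)]
  min48 <- scr[j48, on = .(stay_id, time > lo, time < hi),
               .(m = suppressWarnings(min(x.value))), by = .EACHI]$m
  j7 <- tms[, .(stay_id, t_, lo = t_ - 168, hi = t_)]
  min7d <- scr[j7, on = .(stay_id, time > lo, time < hi),
               .(m = suppressWarnings(min(x.value))), by = .EACHI]$m
  min48[!is.finite(min48)] <- NA_real_
  min7d[!is.finite(min7d)] <- NA_real_

  cr_stage <- rep(NA_integer_, nrow(tms))
  have <- !is.na(cur$cur_scr) & !(is.na(min48) & is.na(min7d))
  if (any(have)) {
    s <- integer(sum(have))
    v <- cur$cur_scr[have]; m48 <- min48[have]; m7 <- min7d[have]
    s[!is.na(m48) & (v - m48 >= 0.3)] <- 1L
    r <- v / m7
    s <- pmax(s, fifelse(!is.na(m7) & r >= 1.5 & r < 2, 1L, 0L))
    s <- pmax(s, fifelse(!is.na(m7) & r >= 2 & r < 3, 2L, 0L))
    s <- pmax(s, fifelse(!is.na(m7) & r >= 3, 3L, 0L))
    cr_stage[have] <- s
  }

  # urine: rolling sums and latest weight
  uo <- cohort$urine_output
  wsum <- function(W) {
    jj <- tms[, .(stay_id, t_, lo = t_ - W, hi = t_)]
    res <- uo[jj, on = .(stay_id, time >= lo, time < hi),
              .(s = sum(volume_ml), n = sum(!is.na(volume_ml))), by = .EACHI]
    list(s = res$s, n = res$n)
  }
  s6 <- wsum(6); s12 <- wsum(12); s24 <- wsum(24)
  wt <- cohort$weights[order(stay_id, time)]
  w_used <- wt[tms, on = .(stay_id, time = t_), roll = Inf, x.weight_kg]

  mk_rate <- function(s, W) {
    r <- s$s / (W * w_used)
    r[is.na(w_used) | s$n == 0 | tms$t_ < W] <- NA_real_
    r
  }
  r6 <- mk_rate(s6, 6); r12 <- mk_rate(s12, 12); r24 <- mk_rate(s24, 24)
  uo_stage <- rep(NA_integer_, nrow(tms))
  any_rate <- !(is.na(r6) & is.na(r12) & is.na(r24))
  us <- integer(nrow(tms))
  us[!is.na(r6) & r6 < 0.5] <- 1L
  us <- pmax(us, fifelse(!is.na(r12) & r12 < 0.5, 2L, 0L))
  us <- pmax(us, fifelse((!is.na(r24) & r24 < 0.3) | (!is.na(r12) & r12 == 0), 3L, 0L))
  uo_stage[any_rate] <- us[any_rate]

  first_rrt <- if (nrow(cohort$rrt))
    cohort$rrt[, .(rrt_start = min(start)), by = stay_id] else
      data.table(stay_id = character(), rrt_start = numeric())
  rrt_at <- first_rrt[tms, on = .(stay_id)]$rrt_start
  rrt_stage <- fifelse(!is.na(rrt_at) & rrt_at <= tms$t_, 3L, 0L)

  if (criteria == "creatinine_only") uo_stage <- rep(NA_integer_, nrow(tms))
  if (criteria == "uo_only") cr_stage <- rep(NA_integer_, nrow(tms))

  overall <- pmax(fifelse(is.na(cr_stage), 0L, cr_stage),
                  fifelse(is.na(uo_stage), 0L, uo_stage),
                  rrt_stage)
  data.table(stay_id = tms$stay_id, t = tms$t_,
             cr_stage = cr_stage, uo_stage = uo_stage,
             rrt_stage = rrt_stage, overall_stage = overall)
}

#' First AKI onset per stay
#'
#' @param cohort An `aki_cohort`.
#' @param assessments Optional precomputed [assess_cohort()] table.
#' @param criteria Passed to [assess_cohort()].
#' @return data.table `stay_id`, `onset` (hours, `NA` when AKI-free).
#' @export
aki_onsets <- function(cohort, assessments = NULL,
                       criteria = c("full", "creatinine_only", "uo_only")) {
  criteria <- match.arg(criteria)
  if (is.null(assessments)) assessments <- assess_cohort(cohort, criteria)
  staged <- assessments[overall_stage >= 1L]
  on <- if (nrow(staged)) staged[, .(onset = min(t)), by = stay_id] else
    data.table(stay_id = character(), onset = numeric())
  out <- on[cohort$stays[, .(stay_id)], on = "stay_id"]
  out[is.na(onset), onset := NA_real_]
  out[]
}
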