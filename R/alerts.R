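# Event-level alert analytics: first-alert matching, lead-time detection
# rates, false-positive taxonomy and alert-burden metrics.

#' Extract alert events from window-level risks
#'
#' An alert fires when the recalibrated risk meets or exceeds the operating
#' threshold. An alert is a true positive when its stay's AKI onset falls
#' within the alert's label interval (`onset - cutoff <= gap + horizon`;
#' censoring guarantees `onset - cutoff > gap`). Other alerts are
#' categorized by the time from cutoff to the stay's onset: up to 48 h ->
#' `fp_24_48`, up to 72 h -> `fp_48_72`, beyond -> `fp_gt72`, no onset ->
#' `fp_no_aki`. Lead time is measured from the prediction cutoff (the
#' moment the prediction is issued) to onset.
#'
#' @param windows Window table (`window_id`, `stay_id`, `cutoff`).
#' @param risks Recalibrated risk per window (no missing values allowed).
#' @param pt Operating threshold.
#' @param onsets data.table `stay_id`, `onset`.
#' @param scheme A [window_scheme()].
#' @return data.table `stay_id`, `cutoff`, `risk`, `matched_onset`,
#'   `lead_time`, `fp_category`.
#' @export
extract_alerts <- function(windows, risks, pt, onsets,
                           scheme = window_scheme()) {
  if (length(risks) != nrow(windows) || anyNA(risks))
    stopf("risks must be non-missing and aligned with windows")
  a <- copy(windows)[, risk := risks][risk >= pt]
  if (!nrow(a)) {
    return(data.table(stay_id = character(), cutoff = numeric(),
                      risk = numeric(), matched_onset = numeric(),
                      lead_time = numeric(), fp_category = character()))
  }
  a[onsets, on = "stay_id", matched_onset := i.onset]
  hor_end <- scheme$gap + scheme$horizon
  a[, dt_on := matched_onset - cutoff]
  a[, fp_category := fifelse(
    is.na(matched_onset), "fp_no_aki",
    fifelse(dt_on <= hor_end, "tp_within_horizon",
            fifelse(dt_on <= 48, "fp_24_48",
                    fifelse(dt_on <= 72, "fp_48_72", "fp_gt72"))))]
  a[, lead_time := fifelse(fp_category == "tp_within_horizon", dt_on, NA_real_)]
  a[, dt_on := NULL]
  a[, .(stay_id, cutoff, risk, matched_onset, lead_time, fp_category)]
}

#' Lead-time detection rates
#'
#' For each bin `h`, the fraction of AKI events whose first true-positive
#' alert precedes the onset by strictly more than `h` hours. Events with no
#' true-positive alert count as undetected at every bin.
#'
#' @param alerts Alert table from [extract_alerts()].
#' @param onsets data.table `stay_id`, `onset` (events = stays with a
#'   non-missing onset).
#' @param bins Lead-time thresholds in hours (default 6, 12, 18, 24).
#' @return data.table `bin`, `n_events`, `n_detected`, `rate`.
#' @export
lead_time_detection <- function(alerts, onsets, bins = c(6, 12, 18, 24)) {
  events <- onsets[!is.na(onset)]
  n_ev <- nrow(events)
  tp <- alerts[fp_category == "tp_within_horizon"]
  leads <- if (nrow(tp)) {
    first_tp <- tp[, .(first_tp_cutoff = min(cutoff)), by = stay_id]
    events[first_tp, on = "stay_id", nomatch = NULL,
           .(stay_id, lead = onset - first_tp_cutoff)]
  } else data.table(stay_id = character(), lead = numeric())
  rbindlist(lapply(bins, function(h) {
    det <- if (n_ev == 0) 0L else sum(leads$lead > h)
    data.table(bin = h, n_events = n_ev, n_detected = det,
               rate = if (n_ev == 0) 0 else det / n_ev)
  }))
}

#' Alert-burden metrics
#'
#' Coverage of an alert runs from its cutoff to the end of its outcome
#' horizon, `[cutoff, cutoff + gap + horizon)`. Time under alert is the
#' per-stay union of coverage intervals, reported raw and capped at
#' discharge; the `_from_gap` variants start coverage at `cutoff + gap`
#' (excluding the gap). A repeat alert is one issued while a previous
#' alert's coverage is still active.
#'
#' @param alerts Alert table from [extract_alerts()].
#' @param stays Stay table with `stay_id`, `discharge_time` (all evaluated
#'   stays, alerting or not).
#' @param scheme A [window_scheme()].
#' @return List of burden statistics (see field names).
#' @export
burden_metrics <- function(alerts, stays, scheme = window_scheme()) {
  patient_days <- sum(stays$discharge_time) / 24
  if (patient_days <= 0) stopf("zero total patient-days")
  total <- nrow(alerts)
  cov_len <- scheme$gap + scheme$horizon

  union_len <- function(starts, ends, cap = Inf) {
    ends <- pmin(ends, cap)
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    if (!length(starts)) return(0)
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    tot <- 0; cur_s <- starts[1]; cur_e <- ends[1]
    for (i in seq_along(starts)[-1]) {
      if (starts[i] <= cur_e) cur_e <- max(cur_e, ends[i])
      else { tot <- tot + cur_e - cur_s; cur_s <- starts[i]; cur_e <- ends[i] }
    }
    tot + cur_e - cur_s
  }

  per_stay <- alerts[order(stay_id, cutoff)][
    , {
      dis <- stays[stay_id == .BY$stay_id, discharge_time]
      prev_end <- shift(cummax(cutoff + cov_len), fill = -Inf)
      .(n_alerts = .N,
        n_repeat = sum(cutoff < prev_end),
        raw = union_len(cutoff, cutoff + cov_len),
        capped = union_len(cutoff, cutoff + cov_len, cap = dis),
        raw_from_gap = union_len(cutoff + scheme$gap, cutoff + cov_len),
        capped_from_gap = union_len(cutoff + scheme$gap, cutoff + cov_len,
                                    cap = dis))
    }, by = stay_id]

  n_stays <- nrow(stays)
  list(total_alerts = total,
       alerts_per_patient_day = total / patient_days,
       alerts_per_shift = total / patient_days / 2,
       time_under_alert_raw = sum(per_stay$raw),
       time_under_alert_capped = sum(per_stay$capped),
       time_under_alert_raw_from_gap = sum(per_stay$raw_from_gap),
       time_under_alert_capped_from_gap = sum(per_stay$capped_from_gap),
       repeat_alerts = sum(per_stay$n_repeat),
       repeat_alert_fraction = if (total > 0) sum(per_stay$n_repeat) / total else 0,
       frac_stays_any_alert = sum(per_stay$n_alerts >= 1) / n_stays,
       frac_stays_ge2_alerts = sum(per_stay$n_alerts >= 2) / n_stays)
}
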