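# Rolling prediction windows, cohort exclusions and grouped CV folds.

#' Rolling prediction window scheme
#'
#' Defaults follow the study design: a 12 h feature window, a 2 h gap to
#' prevent label leakage, a 24 h outcome horizon, predictions refreshed
#' every 6 h.
#'
#' @param feature_window,gap,horizon,stride Hours; all positive, `gap <
#'   horizon`.
#' @return Object of class `window_scheme`.
#' @export
window_scheme <- function(feature_window = 12, gap = 2, horizon = 24, stride = 6) {
  if (any(c(feature_window, gap, horizon, stride) <= 0))
    stopf("all window scheme components must be positive")
  if (gap >= horizon) stopf("gap must be smaller than horizon")
  structure(list(feature_window = feature_window, gap = gap,
                 horizon = horizon, stride = stride),
            class = "window_scheme")
}

#' Apply cohort exclusions
#'
#' Removes stays with age outside 18-88 years, masked age, RRT active at ICU
#' entry, AKI onset before the first eligible cutoff plus gap (prevalent
#' AKI), missing ESKD/baseline status, or a stay too short to fit one
#' feature window plus gap. Each excluded stay is logged once with the first
#' triggered reason, in that priority order.
#'
#' @param cohort An `aki_cohort`.
#' @param onsets data.table `stay_id`, `onset` from [aki_onsets()].
#' @param scheme A [window_scheme()].
#' @return List with `stays` (kept rows of the stay table) and `log`
#'   (data.table `stay_id`, `reason`).
#' @export
apply_exclusions <- function(cohort, onsets, scheme = window_scheme()) {
  stays <- copy(cohort$stays)
  first_gap_end <- scheme$feature_window + scheme$gap
  rrt0 <- cohort$rrt[start <= 0, unique(stay_id)]
  stays[onsets, on = "stay_id", onset := i.onset]

  reason <- rep(NA_character_, nrow(stays))
  pick <- function(cond, r) {
    sel <- which(is.na(reason) & cond)
    reason[sel] <<- r
  }
  pick(!is.na(stays$age) & (stays$age < 18 | stays$age > 88), "age_out_of_range")
  pick(is.na(stays$age), "age_masked")
  pick(stays$stay_id %in% rrt0, "rrt_at_entry")
  pick(!is.na(stays$onset) & stays$onset < first_gap_end, "prevalent_aki")
  pick(is.na(stays$eskd), "missing_status")
  pick(stays$discharge_time < first_gap_end, "too_short")

  keep <- is.na(reason)
  list(stays = stays[keep][, onset := NULL][],
       log = data.table(stay_id = stays$stay_id[!keep],
                        reason = reason[!keep]))
}

#' Build rolling prediction windows for a cohort
#'
#' Cutoffs run from `feature_window` in steps of `stride` while
#' `cutoff + gap <= min(onset, discharge)` (censoring at the first incident
#' AKI). The label is 1 iff the onset falls in the half-open interval
#' `[cutoff + gap, cutoff + gap + horizon)`. Horizons extending past
#' discharge are kept and labelled from observed data.
#'
#' @param stays Kept stay table from [apply_exclusions()].
#' @param onsets data.table `stay_id`, `onset`.
#' @param scheme A [window_scheme()].
#' @return data.table `window_id`, `patient_id`, `stay_id`, `cutoff`,
#'   `label`.
#' @export
build_cohort_windows <- function(stays, onsets, scheme = window_scheme()) {
  s <- stays[, .(patient_id, stay_id, discharge_time)]
  s[onsets, on = "stay_id", onset := i.onset]
  w <- s[, {
    lim <- min(discharge_time, onset, na.rm = TRUE)
    cuts <- seq(scheme$feature_window, by = scheme$stride,
                length.out = max(0, floor((lim - scheme$gap - scheme$feature_window) /
                                            scheme$stride) + 1))
    cuts <- cuts[cuts + scheme$gap <= lim]
    if (length(cuts)) {
      lab <- !is.na(onset) & onset >= cuts + scheme$gap &
        onset < cuts + scheme$gap + scheme$horizon
      .(cutoff = cuts, label = as.integer(lab))
    } else .(cutoff = numeric(), label = integer())
  }, by = .(patient_id, stay_id, onset, discharge_time)]
  w[, c("onset", "discharge_time") := NULL]
  w[, window_id := sprintf("%s@%g", stay_id, cutoff)]
  setcolorder(w, c("window_id", "patient_id", "stay_id", "cutoff", "label"))
  w[]
}

#' Build windows for a single stay
#'
#' Convenience wrapper around [build_cohort_windows()].
#'
#' @param stay One-row stay table.
#' @param onset Onset hour or `NA`.
#' @param scheme A [window_scheme()].
#' @return data.table of windows.
#' @export
build_windows <- function(stay, onset, scheme = window_scheme()) {
  build_cohort_windows(stay, data.table(stay_id = stay$stay_id, onset = onset),
                       scheme)
}

#' Assign patient-grouped cross-validation folds
#'
#' All windows of a patient (across stays) share one fold. Patients are
#' shuffled deterministically under `seed` and dealt round-robin, so fold
#' sizes differ by at most one patient.
#'
#' @param windows Window table with `patient_id`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of folds aligned with `windows` rows.
#' @export
assign_folds <- function(windows, k = 10L, seed = 1L) {
  if (k < 2) stopf("k must be >= 2")
  pats <- unique(windows$patient_id)
  if (length(pats) < k)
    stopf("fewer patients (%d) than folds (%d)", length(pats), k)
  set.seed(seed)
  shuffled <- sample(pats)
  fold_map <- setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  unname(fold_map[windows$patient_id])
}
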