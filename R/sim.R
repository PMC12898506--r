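# Synthetic ICU cohort generator with known ground truth.
#
# Each stay carries latent hourly physiologic trajectories; a latent renal
# "insult" time is drawn from a per-stay constant hazard whose log-rate is
# baseline plus a linear combination of risk drivers. Effect sizes scale both
# the hazard contribution of a driver and the expression of its observable
# precursor (falling mean arterial pressure, falling urine output), so a
# zero-effect configuration plants no predictive signal. Post-insult dynamics
# guarantee that at least the creatinine KDIGO criterion becomes satisfiable
# (a fast initial rise crossing 0.3 mg/dL, then a climb to a plateau
# multiplier drawn from a configurable stage mix) unless discharge intervenes.

#' Simulation configuration for the synthetic ICU cohort
#'
#' @param n_patients Number of patients (each contributes 1-2 ICU stays).
#' @param seed Master seed; per-stay substreams are derived from it so a
#'   given stay's data are stable under cohort-size changes.
#' @param los_lognormal_params Named vector `c(meanlog, sdlog)` of the ICU
#'   length-of-stay distribution, in days.
#' @param baseline_insult_hazard Baseline insult hazard, per hour.
#' @param effect_sizes Named log-hazard-ratio vector for the risk drivers
#'   `map_downtrend`, `low_uo`, `sepsis_flag`, `ckd_flag` and `age`
#'   (the age effect is per decade above 65). The `map_downtrend` and
#'   `low_uo` entries also scale the amplitude of the corresponding
#'   observable precursor trajectories.
#' @param missingness_policy List with `base_rates` (named per-hour sampling
#'   rates for `vitals`, `labs` and `urine`) and `severity_multiplier`
#'   applied to sampling rates after the insult time (informative, MNAR
#'   ordering: sicker patients are measured more often).
#' @param target_window_prevalence Intended window-level AKI prevalence; used
#'   by [calibrate_prevalence()], stored for reference.
#' @param stage_mix Probabilities of the plateau-multiplier buckets
#'   1.5-1.9x, 2.0-2.9x and >= 3.0x (intended KDIGO stage 1/2/3).
#' @param oliguric_fraction Fraction of insult stays whose urine output drops
#'   below 0.5 mL/kg/h post insult (the rest reach AKI via creatinine only).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500L,
                       seed = 1L,
                       los_lognormal_params = c(meanlog = log(3.0), sdlog = 0.6),
                       baseline_insult_hazard = 0.0036,
                       effect_sizes = c(map_downtrend = 1.0, low_uo = 1.0,
                                        sepsis_flag = 0.7, ckd_flag = 0.7,
                                        age = 0.3),
                       missingness_policy = list(
                         base_rates = c(vitals = 0.8, labs = 0.14, urine = 0.95),
                         severity_multiplier = 2.0),
                       target_window_prevalence = 0.119,
                       stage_mix = c(0.5, 0.3, 0.2),
                       oliguric_fraction = 0.6) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stopf("n_patients must be >= 1")
  if (!is.numeric(baseline_insult_hazard) || baseline_insult_hazard < 0 ||
      !is.finite(baseline_insult_hazard))
    stopf("baseline_insult_hazard must be a finite non-negative per-hour rate")
  need <- c("map_downtrend", "low_uo", "sepsis_flag", "ckd_flag", "age")
  if (!all(need %in% names(effect_sizes)))
    stopf("effect_sizes must name all of: %s", paste(need, collapse = ", "))
  if (any(!is.finite(effect_sizes)))
    stopf("effect_sizes must be finite")
  rates <- missingness_policy$base_rates
  if (is.null(rates) || any(!is.finite(rates)) || any(rates <= 0))
    stopf("missingness_policy$base_rates must all be > 0")
  if (is.null(missingness_policy$severity_multiplier) ||
      missingness_policy$severity_multiplier < 0)
    stopf("missingness_policy$severity_multiplier must be >= 0")
  if (!is.null(target_window_prevalence) &&
      (target_window_prevalence <= 0 || target_window_prevalence >= 0.5))
    stopf("target_window_prevalence must lie in (0, 0.5)")
  if (abs(sum(stage_mix) - 1) > 1e-8 || any(stage_mix < 0))
    stopf("stage_mix must be non-negative and sum to 1")
  structure(list(
    n_patients = as.integer(n_patients),
    seed = as.integer(seed),
    los_lognormal_params = los_lognormal_params,
    baseline_insult_hazard = baseline_insult_hazard,
    effect_sizes = effect_sizes,
    missingness_policy = missingness_policy,
    target_window_prevalence = target_window_prevalence,
    stage_mix = stage_mix,
    oliguric_fraction = oliguric_fraction
  ), class = "sim_config")
}

VITAL_STREAMS <- c("hr", "map", "sbp", "dbp", "rr", "temp", "spo2")
LAB_STREAMS <- c("creatinine", "bun", "bicarbonate", "anion_gap", "wbc",
                 "glucose", "hemoglobin", "platelets", "sodium", "potassium",
                 "chloride")

# Latent hourly trajectories plus static attributes for a single stay.
# Returns a list; streams are dense hourly grids (time 0..floor(los)).
simulate_stay_latent <- function(config, patient, stay_idx, forced_insult = NULL,
                                 forced_los = NULL) {
  e <- config$effect_sizes
  los_h <- 24 * rlnorm(1, config$los_lognormal_params[[1]],
                       config$los_lognormal_params[[2]])
  los_h <- min(max(los_h, 18), 21 * 24)
  if (!is.null(forced_los)) los_h <- forced_los

  map_dt <- rbinom(1, 1, 0.25)
  low_uo <- rbinom(1, 1, 0.25)

  age_c <- if (is.na(patient$age)) 0 else (patient$age - 65) / 10
  log_haz <- log(max(config$baseline_insult_hazard, 1e-300)) +
    e[["map_downtrend"]] * map_dt + e[["low_uo"]] * low_uo +
    e[["sepsis_flag"]] * patient$sepsis + e[["ckd_flag"]] * patient$ckd +
    e[["age"]] * age_c
  lambda <- if (config$baseline_insult_hazard == 0) 0 else exp(log_haz)

  insult <- if (!is.null(forced_insult)) {
    forced_insult
  } else if (lambda <= 0) {
    NA_real_
  } else {
    ti <- rexp(1, lambda)
    if (ti < los_h) ti else NA_real_
  }

  tg <- 0:floor(los_h)
  n <- length(tg)
  has_insult <- !is.na(insult)

  # Precursor amplitudes scale with the corresponding effect size: a null
  # configuration (all effects zero) expresses no prodrome.
  amp_map <- if (has_insult && map_dt) 15 * min(abs(e[["map_downtrend"]]), 2.5) else 0
  amp_uo  <- if (has_insult && low_uo) 0.5 * min(abs(e[["low_uo"]]), 2.5) else 0

  prodrome <- function(amp, lead) {
    # 0 before insult-lead, ramps linearly to -amp at insult, holds after.
    if (!has_insult || amp == 0) return(rep(0, n))
    -amp * pmin(pmax((tg - (insult - lead)) / lead, 0), 1)
  }

  # risk-driver phenotypes have chronic observable correlates (scaled by the
  # effect size, so a null configuration expresses none): hypotension-prone
  # stays run a lower baseline MAP, oliguria-prone stays a lower urine rate
  e_map_s <- min(abs(e[["map_downtrend"]]), 2.5) / 2.5
  e_uo_s <- min(abs(e[["low_uo"]]), 2.5) / 2.5
  base_map <- rtnorm(1, 78, 9, 55, 110) - 5 * e_map_s * map_dt
  map <- base_map + prodrome(amp_map, 18) + rnorm(n, 0, 4)
  hr <- rtnorm(1, 85, 10, 50, 130) - prodrome(amp_map * 0.6, 18) + rnorm(n, 0, 4.5)
  sbp <- map * 1.45 + rnorm(n, 0, 6)
  dbp <- map * 0.75 + rnorm(n, 0, 4)
  rr <- rtnorm(1, 17, 3, 8, 35) + rnorm(n, 0, 1.8)
  temp <- rtnorm(1, 36.9, 0.4, 35, 39.5) + rnorm(n, 0, 0.25)
  spo2 <- pmin(100, rtnorm(1, 97, 1.2, 88, 100) +
                 prodrome(amp_map * 0.15, 18) + rnorm(n, 0, 0.9))

  # Creatinine: flat baseline; post insult a fast initial rise (crosses the
  # 0.3 mg/dL criterion within ~3 h of the rise onset) then a linear climb to
  # the plateau multiplier. The short sub-threshold phase keeps pre-onset
  # windows uninformative in the null configuration.
  base_cr <- rlnorm(1, log(0.9), 0.22) * (1 + 0.6 * patient$ckd)
  bucket <- sample.int(3, 1, prob = config$stage_mix)
  plateau_mult <- c(runif(1, 1.6, 1.9), runif(1, 2.0, 2.9), runif(1, 3.0, 4.0))[bucket]
  lag <- runif(1, 1, 3)
  rise_dur <- runif(1, 14, 26)
  cr <- rep(base_cr, n)
  if (has_insult) {
    # steep initial rise: the 0.3 mg/dL criterion is crossed within ~1.2 h
    # of the rise onset, so pre-onset labs carry almost no sub-threshold tell
    t0 <- insult + lag
    fast <- pmin(pmax(tg - t0, 0), 2) * 0.25
    slow_span <- max(plateau_mult * base_cr - (base_cr + 0.5), 0)
    slow <- pmin(pmax(tg - (t0 + 2), 0) / rise_dur, 1) * slow_span
    cr <- pmin(base_cr + fast + slow, plateau_mult * base_cr)
  }
  cr <- pmax(cr + rnorm(n, 0, 0.03), 0.1)

  base_bun <- rtnorm(1, 18, 5, 5, 60) * (1 + 0.4 * patient$ckd)
  bun <- rep(base_bun, n)
  if (has_insult) {
    span <- base_bun * (plateau_mult - 1) * 0.8
    bun <- base_bun + pmin(pmax(tg - (insult + lag), 0) / (rise_dur + 4), 1) * span
  }
  bun <- pmax(bun + rnorm(n, 0, 1.5), 3)

  # downstream metabolic consequences ramp in only after the typical
  # criterion-crossing delay, so they trail rather than precede the label
  post24 <- function(amp) {
    if (!has_insult) return(rep(0, n))
    amp * pmin(pmax(tg - (insult + lag + 6), 0) / 24, 1)
  }
  bicarbonate <- pmax(rtnorm(1, 24, 2.5, 14, 34) + post24(-3) + rnorm(n, 0, 0.8), 8)
  anion_gap <- pmax(rtnorm(1, 13, 2, 6, 24) + post24(3) + rnorm(n, 0, 0.9), 3)
  wbc <- pmax(rlnorm(1, log(9), 0.3) * (1 + 0.4 * patient$sepsis) +
                post24(2) + rnorm(n, 0, 0.8), 1)
  glucose <- pmax(rtnorm(1, 132, 28, 60, 320) + rnorm(n, 0, 12), 40)
  hemoglobin <- pmax(rtnorm(1, 11.5, 1.8, 6, 18) + rnorm(n, 0, 0.3), 4)
  platelets <- pmax(rtnorm(1, 220, 70, 40, 600) + rnorm(n, 0, 10), 10)
  sodium <- rtnorm(1, 139, 3, 125, 155) + rnorm(n, 0, 1.2)
  potassium <- pmax(rtnorm(1, 4.1, 0.4, 2.5, 6.5) + rnorm(n, 0, 0.15), 2)
  chloride <- rtnorm(1, 104, 4, 88, 120) + rnorm(n, 0, 1.5)

  # Urine output latent rate in mL/kg/h; realized hourly as rate*weight.
  base_rate <- max(rtnorm(1, 1.4, 0.3, 0.5, 2.6) - 0.25 * e_uo_s * low_uo, 0.75)
  uo_rate <- base_rate + prodrome(amp_uo, 12)
  uo_rate <- pmax(uo_rate, 0.6)   # prodrome never crosses the staging threshold
  oliguric <- has_insult && runif(1) < config$oliguric_fraction
  if (oliguric) {
    drop <- pmin(pmax(tg - insult, 0) / 1.5, 1)
    floor_rate <- runif(1, 0.1, 0.25)
    hold <- tg <= insult + 36
    uo_rate <- ifelse(hold, uo_rate * (1 - drop) + floor_rate * drop,
                      pmax(uo_rate * 0.9, 0.7))
  }
  uo_rate <- pmax(uo_rate + rnorm(n, 0, 0.05), 0)

  weight <- rtnorm(1, 80, 16, 40, 160)
  w_times <- 0
  if (runif(1) < 0.5) w_times <- c(0, round(runif(1, 0.3, 0.7) * los_h, 1))
  weights <- data.table(time = w_times,
                        weight_kg = round(weight + c(0, rnorm(length(w_times) - 1, 0, 1)), 1))
  if (runif(1) < 0.02) weights <- weights[0]   # no weight ever charted

  # RRT: rare at ICU entry (exclusion pathway); severe AKI may start RRT late.
  rrt <- data.table(start = numeric(), end = numeric())
  if (runif(1) < 0.01) {
    rrt <- data.table(start = 0, end = min(72, los_h))
  } else if (has_insult && bucket == 3L && runif(1) < 0.4) {
    rs <- insult + lag + 4 + runif(1, 6, 24)
    if (rs < los_h) rrt <- data.table(start = rs, end = min(rs + 72, los_h))
  }

  treatments <- list()
  if (patient$shock) {
    dur <- runif(1, 12, 72)
    treatments$norepi <- data.table(drug = "norepinephrine", start = 0,
                                    end = min(dur, los_h),
                                    dose = round(runif(1, 0.05, 0.5), 3))
  }
  # pressor support accompanying the hypotensive prodrome; expression scales
  # with the planted precursor effect so a null configuration has none
  p_vaso <- 0.4 * min(max(abs(e[["map_downtrend"]]), abs(e[["low_uo"]])) / 2, 1)
  if (has_insult && map_dt && runif(1) < p_vaso) {
    st <- max(insult - 6, 0)
    treatments$norepi2 <- data.table(drug = "norepinephrine", start = st,
                                     end = min(st + runif(1, 12, 48), los_h),
                                     dose = round(runif(1, 0.1, 0.6), 3))
  }
  if (patient$hypertension && runif(1) < 0.3)
    treatments$acei <- data.table(drug = "acei_arb", start = 0, end = los_h, dose = NA_real_)
  if (patient$contrast)
    treatments$contrast <- data.table(drug = "contrast", start = runif(1, 0, min(24, los_h)),
                                      end = NA_real_, dose = NA_real_)
  treatments <- if (length(treatments)) rbindlist(treatments) else
    data.table(drug = character(), start = numeric(), end = numeric(), dose = numeric())

  vit <- data.table(time = rep(tg, 7),
                    variable = rep(VITAL_STREAMS, each = n),
                    value = round(c(hr, map, sbp, dbp, rr, temp, spo2), 2))
  lab <- data.table(time = rep(tg, 11),
                    variable = rep(LAB_STREAMS, each = n),
                    value = round(c(cr, bun, bicarbonate, anion_gap, wbc, glucose,
                                    hemoglobin, platelets, sodium, potassium,
                                    chloride), 3))

  list(discharge_time = los_h,
       insult_time = insult,
       map_downtrend = map_dt, low_uo = low_uo,
       plateau_mult = if (has_insult) plateau_mult else NA_real_,
       oliguric = if (has_insult) as.integer(oliguric) else NA_integer_,
       true_weight = weight,
       vitals = vit, labs = lab,
       uo_hourly = data.table(time = tg, volume_ml = round(uo_rate * weight, 1)),
       weights = weights, rrt = rrt, treatments = treatments)
}

#' Thin a stay's dense latent streams into informatively sampled observations
#'
#' Vitals and labs are thinned by Bernoulli sampling of the hourly latent
#' grid at the per-stream base rate; after the insult time the rate is
#' multiplied by the severity multiplier (capped at 1 per hour), emulating
#' concern-driven (MNAR) ordering. Urine output is re-charted at the urine
#' rate with volume accumulated since the previous charted event, conserving
#' total volume. RRT episodes, weights and static fields are never removed.
#'
#' @param stay A latent stay as produced internally by [simulate_cohort()]
#'   (list with `vitals`, `labs`, `uo_hourly`, `insult_time`, ...).
#' @param policy Missingness policy (see [sim_config()]).
#' @return The stay with `vitals`, `labs` thinned and `urine_output` charted.
#' @export
apply_missingness <- function(stay, policy) {
  rates <- policy$base_rates
  if (any(!is.finite(rates)) || any(rates <= 0)) stopf("sampling rates must be > 0")
  mult <- policy$severity_multiplier
  if (is.null(mult) || mult < 0) stopf("severity_multiplier must be >= 0")
  ins <- stay$insult_time

  p_keep <- function(times, base) {
    r <- rep(base, length(times))
    if (!is.na(ins)) r[times > ins] <- r[times > ins] * mult
    pmin(r, 1)
  }
  thin <- function(dt_, base) {
    if (!nrow(dt_)) return(dt_)
    dt_[runif(nrow(dt_)) < p_keep(dt_$time, base)]
  }
  out <- stay
  out$vitals <- thin(stay$vitals, rates[["vitals"]])
  out$labs <- thin(stay$labs, rates[["labs"]])

  uo <- stay$uo_hourly
  if (nrow(uo)) {
    chart <- runif(nrow(uo)) < p_keep(uo$time, rates[["urine"]])
    # charted volume accumulates since the previous charted hour
    grp <- rev(cumsum(rev(as.integer(chart))))
    keep_dt <- data.table(time = uo$time, volume_ml = uo$volume_ml, grp = grp, chart = chart)
    charted <- keep_dt[grp > 0, .(time = time[chart][1] %||% NA_real_,
                                  volume_ml = sum(volume_ml)), by = grp]
    charted <- charted[!is.na(time)][order(time)][, grp := NULL]
    # the hourly total at time t covers [t, t+1); chart it at the hour end
    charted[, time := time + 1]
    charted <- charted[time <= stay$discharge_time]
    out$urine_output <- charted
  } else {
    out$urine_output <- data.table(time = numeric(), volume_ml = numeric())
  }
  out$uo_hourly <- NULL
  out
}

#' Simulate a synthetic ICU cohort with known ground truth
#'
#' @param config A [sim_config()].
#' @param thin Apply the missingness policy (default). `thin = FALSE`
#'   returns the dense hourly latent streams (urine charted every hour).
#' @param forced_insults Optional named numeric vector `stay_id -> hour`
#'   forcing insult times (testing hook for planting known trajectories).
#' @param forced_los Optional named numeric vector `stay_id -> hours`
#'   forcing stay length (same testing hook).
#' @return An object of class `aki_cohort`: a list of data.tables
#'   (`stays`, `vitals`, `labs`, `urine_output`, `weights`, `treatments`,
#'   `rrt`, `ground_truth`) plus the `config` used. Times are hours from
#'   ICU admission; intervals are half-open `[start, end)`.
#' @export
simulate_cohort <- function(config, thin = TRUE, forced_insults = NULL,
                            forced_los = NULL) {
  stopifnot(inherits(config, "sim_config"))
  races <- c("White", "Black", "Hispanic", "Asian", "Other")
  units <- c("MICU", "SICU", "CCU", "NeuroICU", "CTICU")

  stays_l <- list(); gt_l <- list()
  ev <- list(vitals = list(), labs = list(), urine_output = list(),
             weights = list(), treatments = list(), rrt = list())

  for (i in seq_len(config$n_patients)) {
    set.seed(substream_seed(config$seed, i))
    pid <- sprintf("P%05d", i)
    true_age <- round(rtnorm(1, 65, 15, 18, 100))
    masked <- runif(1) < 0.02
    patient <- list(
      age = if (masked) NA_real_ else true_age,
      true_age = true_age,
      sex = sample(c("F", "M"), 1, prob = c(0.46, 0.54)),
      race = sample(races, 1, prob = c(0.60, 0.15, 0.10, 0.08, 0.07)),
      ckd = rbinom(1, 1, 0.12), diabetes = rbinom(1, 1, 0.25),
      sepsis = rbinom(1, 1, 0.17), shock = rbinom(1, 1, 0.20),
      hypertension = rbinom(1, 1, 0.55), cirrhosis = rbinom(1, 1, 0.05),
      ami = rbinom(1, 1, 0.06), ahf = rbinom(1, 1, 0.12),
      contrast = rbinom(1, 1, 0.015), covid = rbinom(1, 1, 0.02),
      eskd = if (runif(1) < 0.01) NA_integer_ else 0L
    )
    n_stays <- 1L + (runif(1) < 0.05)
    for (s in seq_len(n_stays)) {
      sid <- sprintf("%s-%d", pid, s)
      set.seed(substream_seed(config$seed, i * 8L + s))
      stay <- simulate_stay_latent(config, patient, s,
                                   forced_insult = if (!is.null(forced_insults) &&
                                                       sid %in% names(forced_insults))
                                     forced_insults[[sid]] else NULL,
                                   forced_los = if (!is.null(forced_los) &&
                                                    sid %in% names(forced_los))
                                     forced_los[[sid]] else NULL)
      obs <- if (thin) apply_missingness(stay, config$missingness_policy) else {
        o <- stay
        o$urine_output <- copy(stay$uo_hourly)[, time := time + 1][time <= stay$discharge_time]
        o$uo_hourly <- NULL
        o
      }
      stays_l[[sid]] <- data.table(
        patient_id = pid, stay_id = sid, age = patient$age, sex = patient$sex,
        race = patient$race,
        unit_type = sample(units, 1, prob = c(0.35, 0.25, 0.15, 0.14, 0.11)),
        ckd = patient$ckd, diabetes = patient$diabetes, sepsis = patient$sepsis,
        shock = patient$shock, hypertension = patient$hypertension,
        cirrhosis = patient$cirrhosis, ami = patient$ami, ahf = patient$ahf,
        contrast = patient$contrast, covid = patient$covid, eskd = patient$eskd,
        admission_time = 0, discharge_time = stay$discharge_time)
      gt_l[[sid]] <- data.table(
        patient_id = pid, stay_id = sid, insult_time = stay$insult_time,
        plateau_mult = stay$plateau_mult, oliguric = stay$oliguric,
        map_downtrend = stay$map_downtrend, low_uo = stay$low_uo)
      for (nm in names(ev)) {
        tab <- obs[[nm]]
        if (nrow(tab)) ev[[nm]][[sid]] <- cbind(data.table(stay_id = sid), tab)
      }
    }
  }

  empty <- list(
    vitals = data.table(stay_id = character(), time = numeric(),
                        variable = character(), value = numeric()),
    labs = data.table(stay_id = character(), time = numeric(),
                      variable = character(), value = numeric()),
    urine_output = data.table(stay_id = character(), time = numeric(),
                              volume_ml = numeric()),
    weights = data.table(stay_id = character(), time = numeric(),
                         weight_kg = numeric()),
    treatments = data.table(stay_id = character(), drug = character(),
                            start = numeric(), end = numeric(), dose = numeric()),
    rrt = data.table(stay_id = character(), start = numeric(), end = numeric()))

  cohort <- list(stays = rbindlist(stays_l), ground_truth = rbindlist(gt_l, fill = TRUE))
  for (nm in names(ev))
    cohort[[nm]] <- if (length(ev[[nm]])) rbindlist(ev[[nm]]) else empty[[nm]]
  for (nm in c("vitals", "labs", "urine_output"))
    setkeyv(cohort[[nm]], c("stay_id", "time"))
  cohort$config <- config
  class(cohort) <- "aki_cohort"
  cohort
}

#' @export
print.aki_cohort <- function(x, ...) {
  cat(sprintf("<aki_cohort> %d stays / %d patients, %d lab rows, %d vital rows\n",
              nrow(x$stays), length(unique(x$stays$patient_id)),
              nrow(x$labs), nrow(x$vitals)))
  invisible(x)
}

#' Calibrate the baseline insult hazard to a target window-level prevalence
#'
#' Bisection on the baseline hazard: each candidate is evaluated by
#' simulating a cohort (same seed, common random numbers), running the full
#' KDIGO labelling, exclusion and windowing pipeline, and measuring the
#' realized window-level label prevalence.
#'
#' @param config A [sim_config()].
#' @param target Target prevalence, in (0, 0.5).
#' @param n_stays Number of patients per evaluation (>= 500 per contract).
#' @param tol Acceptable absolute deviation (fraction), default 0.02.
#' @param max_iter Bisection iterations.
#' @param scheme Window scheme used for evaluation.
#' @return The config with `baseline_insult_hazard` replaced.
#' @export
calibrate_prevalence <- function(config, target, n_stays = 500L, tol = 0.02,
                                 max_iter = 12L, scheme = window_scheme()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(target) || target <= 0 || target >= 0.5)
    stopf("target prevalence must lie in the open interval (0, 0.5)")
  eval_prev <- function(h) {
    cfg <- config
    cfg$baseline_insult_hazard <- h
    cfg$n_patients <- as.integer(max(n_stays, 500L))
    cohort <- simulate_cohort(cfg)
    onsets <- aki_onsets(cohort)
    kept <- apply_exclusions(cohort, onsets, scheme)
    w <- build_cohort_windows(kept$stays, onsets, scheme)
    if (!nrow(w)) 0 else mean(w$label)
  }
  lo <- 1e-5; hi <- 0.05
  p_lo <- eval_prev(lo); p_hi <- eval_prev(hi)
  if (target < p_lo - tol || target > p_hi + tol)
    stopf("target prevalence %.3f unattainable; achievable range about [%.3f, %.3f]",
          target, p_lo, p_hi)
  if (abs(p_lo - target) <= tol) { config$baseline_insult_hazard <- lo; return(config) }
  if (abs(p_hi - target) <= tol) { config$baseline_insult_hazard <- hi; return(config) }
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)   # bisect on the log scale (hazard spans decades)
    p_mid <- eval_prev(mid)
    if (abs(p_mid - target) <= tol) {
      config$baseline_insult_hazard <- mid
      config$target_window_prevalence <- target
      return(config)
    }
    if (p_mid < target) lo <- mid else hi <- mid
  }
  stopf("prevalence calibration did not converge to within %.3f of target %.3f",
        tol, target)
}

#' Write a cohort as delimited tables
#'
#' Writes `stays.csv`, `vitals.csv`, `labs.csv`, `urine_output.csv`,
#' `weights.csv`, `treatments.csv`, `rrt.csv` and `ground_truth.csv`.
#' Times are hours from ICU admission; volumes mL; weights kg.
#'
#' @param cohort An `aki_cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("stays", "vitals", "labs", "urine_output", "weights",
               "treatments", "rrt", "ground_truth"))
    fwrite(cohort[[nm]], file.path(dir, paste0(nm, ".csv")))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()] (or any tables matching its schema)
#' @param dir Directory containing the cohort tables.
#' @return An `aki_cohort` (without a `config` element).
#' @export
read_cohort <- function(dir) {
  cohort <- list()
  for (nm in c("stays", "vitals", "labs", "urine_output", "weights",
               "treatments", "rrt", "ground_truth")) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stopf("missing cohort table: %s", f)
    cohort[[nm]] <- fread(f)
  }
  for (nm in c("vitals", "labs", "urine_output"))
    setkeyv(cohort[[nm]], c("stay_id", "time"))
  class(cohort) <- "aki_cohort"
  cohort
}
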