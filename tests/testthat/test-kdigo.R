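test_that("creatinine baselines use strictly prior half-open lookbacks", {
  b <- baseline_scr(data.frame(time = 0, value = 1.0), t = 0)
  expect_true(is.na(b$min48) && is.na(b$min7d))

  b <- baseline_scr(data.frame(time = c(0, 30), value = c(1.2, 0.9)), t = 40)
  expect_equal(b$min48, 0.9)
  expect_equal(b$min7d, 0.9)

  b <- baseline_scr(data.frame(time = c(0, 100), value = c(0.8, 1.5)), t = 120)
  expect_equal(b$min48, 1.5)   # only t = 100 lies within 48 h
  expect_equal(b$min7d, 0.8)

  expect_error(baseline_scr(data.frame(time = c(5, 1), value = c(1, 1)), 10),
               "sorted")
})

test_that("creatinine staging follows the rise/ratio bands with max-stage rule", {
  expect_equal(stage_creatinine(1.4, list(min48 = 1.0, min7d = 1.0)), 1L)
  expect_equal(stage_creatinine(2.0, list(min48 = NA, min7d = 1.0)), 2L)
  expect_equal(stage_creatinine(3.1, list(min48 = 3.0, min7d = 1.0)), 3L)
  # half-open bands, boundary behavior
  expect_equal(stage_creatinine(1.5, list(min48 = NA, min7d = 1.0)), 1L)
  expect_equal(stage_creatinine(2.999, list(min48 = NA, min7d = 1.0)), 2L)
  expect_equal(stage_creatinine(3.0, list(min48 = NA, min7d = 1.0)), 3L)
  expect_equal(stage_creatinine(1.29, list(min48 = 1.0, min7d = 1.0)), 0L)
  expect_true(is.na(stage_creatinine(1.4, list(min48 = NA, min7d = NA))))
  expect_error(stage_creatinine(0, list(min48 = 1, min7d = 1)), "> 0")
})

test_that("urine rates are weight-normalized windowed sums with missing rules", {
  uo <- data.frame(time = 24, volume_ml = 240)
  w <- data.frame(time = 0, weight_kg = 80)
  r <- uo_rates(data.frame(time = seq(24.5, 29.5, 1), volume_ml = rep(40, 6)),
                w, t = 30)
  expect_equal(r$rate6, 240 / (6 * 80))

  r <- uo_rates(data.frame(time = c(10, 25), volume_ml = c(600, 100)),
                data.frame(time = 0, weight_kg = 50), t = 30)
  expect_equal(r$rate6, 100 / (6 * 50))
  expect_equal(r$rate24, 700 / (24 * 50))

  r <- uo_rates(uo, data.frame(time = numeric(), weight_kg = numeric()), t = 30)
  expect_true(is.na(r$rate6) && is.na(r$rate12) && is.na(r$rate24))
  expect_true(is.na(stage_urine(r)))

  # no full window inside the stay yet
  r <- uo_rates(uo, w, t = 4)
  expect_true(is.na(r$rate6))
  expect_error(uo_rates(data.frame(time = 1, volume_ml = -5), w, 10), ">= 0")
})

test_that("urine staging thresholds are strict with the anuria rule", {
  expect_equal(stage_urine(list(rate6 = 0.375, rate12 = 0.6, rate24 = 0.7)), 1L)
  expect_equal(stage_urine(list(rate6 = 0.6, rate12 = 0, rate24 = 0.6)), 3L)
  expect_equal(stage_urine(list(rate6 = 0.5, rate12 = 0.5, rate24 = 0.3)), 0L)
  expect_equal(stage_urine(list(rate6 = 0.6, rate12 = 0.4, rate24 = 0.4)), 2L)
  expect_equal(stage_urine(list(rate6 = NA, rate12 = NA, rate24 = 0.2)), 3L)
})

test_that("RRT forces stage 3 and bounds the onset", {
  stay <- list(scr = data.frame(time = c(1, 20), value = c(1.0, 1.0)),
               uo = data.frame(time = numeric(), volume_ml = numeric()),
               weights = data.frame(time = numeric(), weight_kg = numeric()),
               rrt = data.frame(start = 36, end = 80),
               discharge_time = 90)
  a <- assess_kdigo(stay, 36)
  expect_equal(a$rrt_stage, 3L)
  expect_equal(a$overall_stage, 3L)
  expect_equal(aki_onset(stay), 36)
  # adding an RRT episode never delays the onset
  stay2 <- stay; stay2$rrt <- data.frame(start = c(12, 36), end = c(20, 80))
  expect_lte(aki_onset(stay2), aki_onset(stay))
})

test_that("the vectorized labeler matches per-timestamp brute-force assessment", {
  co <- small_cohort()$cohort
  ass <- assess_cohort(co)
  for (sid in co$stays$stay_id) {
    stay <- stay_for(co, sid)
    sub <- ass[stay_id == sid]
    for (i in seq_len(nrow(sub))) {
      ref <- assess_kdigo(stay, sub$t[i])
      expect_identical(sub$cr_stage[i], ref$cr_stage)
      expect_identical(sub$uo_stage[i], ref$uo_stage)
      expect_identical(sub$rrt_stage[i], ref$rrt_stage)
      expect_identical(sub$overall_stage[i], as.integer(ref$overall_stage))
    }
  }
  # onsets agree with the scalar path
  on <- aki_onsets(co, ass)
  for (sid in co$stays$stay_id) {
    expect_equal(on[stay_id == sid, onset], aki_onset(stay_for(co, sid)))
  }
})

test_that("assessments are causal: future perturbations change nothing", {
  co <- small_cohort()$cohort
  on <- aki_onsets(co)
  sids <- head(on[!is.na(onset), stay_id], 5)
  for (sid in sids) {
    stay <- stay_for(co, sid)
    t_star <- max(6, floor(on[stay_id == sid, onset]) - 4)
    before <- assess_kdigo(stay, t_star)
    pert <- stay
    pert$scr <- rbind(stay$scr[stay$scr$time <= t_star, ],
                      data.frame(time = t_star + 0.5, value = 25))
    pert$uo <- stay$uo[stay$uo$time <= t_star, ]
    pert$rrt <- rbind(stay$rrt, data.frame(start = t_star + 1, end = t_star + 10))
    after <- assess_kdigo(pert, t_star)
    expect_identical(before, after)
  }
})

test_that("deleting all weights reduces staging to the creatinine criteria", {
  co <- small_cohort()$cohort
  co2 <- co
  co2$weights <- co$weights[0]
  on_nw <- aki_onsets(co2)
  on_cr <- aki_onsets(co, criteria = "creatinine_only")
  expect_equal(as.data.frame(on_nw), as.data.frame(on_cr))
})

test_that("restricted label criteria are subsets of the full criteria", {
  co <- small_cohort()$cohort
  n_full <- sum(!is.na(aki_onsets(co)$onset))
  n_cr <- sum(!is.na(aki_onsets(co, criteria = "creatinine_only")$onset))
  n_uo <- sum(!is.na(aki_onsets(co, criteria = "uo_only")$onset))
  expect_lte(n_cr, n_full)
  expect_lte(n_uo, n_full)
})
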