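test_that("flagging is inclusive at the threshold", {
  rec <- make_records(4, delta_dco = c(0, 199, 200, 350))
  out <- flag_records(rec, analysis_config())
  expect_identical(out$flagged, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("relative flagging uses a per-patient prescription threshold", {
  cfg <- analysis_config(relative_threshold_pct = 3)
  rec <- make_records(2, delta_dco = c(209, 210), prescription = 6996)
  out <- flag_records(rec, cfg)
  expect_equal(unique(out$flag_threshold_used_cgy), 209.88)
  expect_identical(out$flagged, c(FALSE, TRUE))

  rec$prescription_cgy <- NA_real_
  expect_error(flag_records(rec, cfg), "prescription")
})

test_that("an all-identical cohort flags nothing", {
  rec <- make_records(10, delta_dco = 0, identical_pair = TRUE)
  out <- flag_records(rec, analysis_config())
  expect_equal(sum(out$flagged), 0)
})

test_that("raising the threshold never increases the flagged count", {
  set.seed(71)
  rec <- make_records(50, delta_dco = runif(50, 0, 600))
  counts <- vapply(c(50, 100, 200, 400), function(thr)
    sum(flag_records(rec, analysis_config(flag_threshold_cgy = thr))$flagged),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("summarize_cohort reproduces hand-computed quantiles", {
  # |deltas| {0, 0, 100, 400}: median 50, Q90 310 under linear interpolation
  rec <- make_records(4, delta_dco = c(0, 0, 100, 400))
  rec <- flag_records(rec, analysis_config())
  s <- summarize_cohort(rec, analysis_config())
  row <- s$organ_table[s$organ_table$organ == "brainstem", ]
  expect_equal(row$abs_ddmax_median_cgy, 50)
  expect_equal(row$abs_ddmax_q90_cgy, 310)
  expect_equal(row$n, 4)
  expect_equal(row$n_flagged, 1)
})

test_that("a single record is its own summary and absent organs get N = 0 rows", {
  rec <- flag_records(make_records(1, delta_dco = 120, dsc = 0.8),
                      analysis_config())
  s <- summarize_cohort(rec, analysis_config(),
                        organs = c("brainstem", "larynx"))
  expect_equal(s$organ_table$n, c(1, 0))
  row <- s$organ_table[1, ]
  expect_equal(row$dsc_mean, 0.8)
  expect_equal(row$abs_ddmax_median_cgy, 120)
  expect_equal(row$abs_ddmax_q90_cgy, 120)
  expect_true(is.na(s$organ_table$dsc_mean[2]))
  expect_equal(s$pooled$n, 1)
})

test_that("pooled coverage thresholds are the stated percentiles", {
  set.seed(72)
  n <- 40
  rec <- make_records(n, delta_dco = runif(n, 0, 300),
                      dsc = runif(n), sdsc = runif(n), hd = runif(n, 0, 20))
  rec <- flag_records(rec, analysis_config())
  s <- summarize_cohort(rec, analysis_config())
  expect_equal(s$pooled$dsc_p10, unname(quantile(rec$dsc, 0.1, type = 7)))
  expect_equal(s$pooled$sdsc_p10, unname(quantile(rec$sdsc, 0.1, type = 7)))
  expect_equal(s$pooled$hd_p90_mm, unname(quantile(rec$hd_mm, 0.9, type = 7)))
  expect_equal(s$pooled$frac_abs_ddmax_below_threshold,
               mean(rec$abs_delta_dmax_cgy < 200))
})

test_that("binned flag proportions partition the records", {
  cfg <- analysis_config()
  # one bin, half flagged
  rec <- flag_records(make_records(4, delta_dco = c(300, 250, 0, 10),
                                   dsc = 0.55), cfg)
  curve <- binned_flag_proportions(rec, "dsc", cfg)
  pop <- curve[curve$n > 0, ]
  expect_equal(nrow(pop), 1)
  expect_equal(pop$flagged_fraction, 0.5)
  expect_equal(sum(curve$n), nrow(rec))

  # DSC exactly 1.0 lands in the closed top bin
  rec2 <- flag_records(make_records(1, dsc = 1), cfg)
  curve2 <- binned_flag_proportions(rec2, "dsc", cfg)
  expect_equal(curve2$n[curve2$bin_lo == 0.9], 1)

  # two-bin construction: {3 of 4 flagged} and {0 of 6}
  rec3 <- flag_records(make_records(
    10, delta_dco = c(300, 300, 300, 0, rep(0, 6)),
    dsc = c(rep(0.35, 4), rep(0.75, 6))), cfg)
  curve3 <- binned_flag_proportions(rec3, "dsc", cfg)
  expect_equal(curve3$flagged_fraction[curve3$bin_lo == 0.3], 0.75)
  expect_equal(curve3$flagged_fraction[curve3$bin_lo == 0.7], 0)
  expect_true(is.na(curve3$flagged_fraction[curve3$bin_lo == 0.5]))
  expect_equal(sum(curve3$n), 10)
})

test_that("HD curves use 2 mm bins and conserve counts", {
  cfg <- analysis_config()
  set.seed(73)
  rec <- flag_records(make_records(30, delta_dco = runif(30, 0, 400),
                                   hd = runif(30, 0, 12)), cfg)
  curve <- binned_flag_proportions(rec, "hd", cfg)
  expect_equal(unique(round(curve$bin_hi - curve$bin_lo, 9)), 2)
  expect_equal(sum(curve$n), 30)
})

test_that("proximity stratification reports flagged fractions within the cutoff", {
  cfg <- analysis_config()
  rec <- flag_records(make_records(
    6, delta_dco = c(300, 300, 300, 300, 0, 0),
    dist = c(5, 10, 20, 40, 5, 60),
    dsc = c(0.95, 0.5, 0.95, 0.6, 0.9, 0.9)), cfg)
  strat <- proximity_stratified_flags(rec, cfg)
  expect_equal(strat$n_flagged, 4)
  expect_equal(strat$n_within, 3)
  expect_equal(strat$fraction_within, 0.75)
  expect_equal(strat$high_dsc$n, 2)               # flagged with DSC > 0.9
  expect_equal(strat$high_dsc$fraction_within, 1) # both at 5 and 20 mm

  none <- flag_records(make_records(3, delta_dco = 0), cfg)
  s0 <- proximity_stratified_flags(none, cfg)
  expect_equal(s0$n_flagged, 0)
  expect_true(is.na(s0$fraction_within))
})

test_that("sensitivity scenarios rerun flagging under the stated rules", {
  cfg <- analysis_config()
  rec <- make_records(6, delta_dco = c(0, 150, 190, 210, 300, 100),
                      prescription = 6000)
  sens <- sensitivity_run(rec, cfg)
  expect_setequal(names(sens$scenarios),
                  c("baseline", "min_plan_dose", "relative_3pct",
                    "relative_5pct"))
  # all patients at 6000 cGy >= 4000: inclusion scenario == baseline
  expect_equal(sens$scenarios$min_plan_dose$n_flagged,
               sens$scenarios$baseline$n_flagged)
  expect_equal(sens$scenarios$min_plan_dose$n, sens$scenarios$baseline$n)
  # 3% of 6000 = 180: the 190 cGy record flags at 3% but not at 200 absolute
  expect_equal(sens$scenarios$baseline$n_flagged, 2)
  expect_equal(sens$scenarios$relative_3pct$n_flagged, 3)
  # 5% of 6000 = 300: inclusive boundary keeps the 300 record
  expect_equal(sens$scenarios$relative_5pct$n_flagged, 1)

  low_rx <- rec; low_rx$prescription_cgy <- NA_real_
  expect_error(sensitivity_run(low_rx, cfg), "prescription")
})

test_that("the inclusion filter drops low-prescription patients", {
  cfg <- analysis_config()
  rec <- rbind(make_records(3, delta_dco = 300, prescription = 6996,
                            patient = "P001"),
               make_records(2, delta_dco = 300, prescription = 1400,
                            patient = "P002"))
  sens <- sensitivity_run(rec, cfg)
  expect_equal(sens$scenarios$baseline$n, 5)
  expect_equal(sens$scenarios$min_plan_dose$n, 3)
})

test_that("analysis_config validates its thresholds", {
  expect_error(analysis_config(flag_threshold_cgy = 0))
  expect_error(analysis_config(relative_threshold_pct = -1), "positive")
  expect_error(analysis_config(min_plan_dose_cgy = 0), "positive")
})
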