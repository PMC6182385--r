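test_that("the canonical non-sequential RLC matches its design constraints", {
  seq <- default_rlc_sequence()
  expect_equal(nrow(seq$steps), 9)
  expect_true(all(seq$steps$duration_s == 30))
  expect_equal(sum(seq$steps$duration_s), 270)
  sched <- measurement_schedule(seq)
  # dark-adapted reference opens the schedule
  expect_equal(sched$step_index[1], 0L)
  expect_equal(sched$par[1], 0)
  # the step measured 180 s into the protocol is at PAR 470
  expect_equal(sched$par[sched$timestamp_s == 180], 470)
  # after 270 s PAR drops to the growth irradiance for the final step
  expect_equal(tail(seq$steps$par, 1), 74)
  expect_equal(max(sched$timestamp_s), 300)
  # revisited light levels make the design non-sequential
  expect_true(all(c(300, 470, 74) %in%
                    seq$steps$par[duplicated(seq$steps$par)]))
})

test_that("induction-recovery design has two segments and a regular schedule", {
  seq <- induction_recovery_sequence(par = 600)
  expect_equal(seq$steps$par, c(600, 0))
  expect_equal(seq$steps$duration_s, c(1200, 900))
  sched <- measurement_schedule(seq)
  expect_equal(nrow(sched), 1 + 20 + 15)
  expect_true(all(diff(sched$timestamp_s) > 0))
  expect_error(light_sequence(c(300, 0, 0), c(10, 10, 10),
                              design = "induction_recovery"),
               class = "frrf_error")
})

test_that("pairing a noiseless synthetic RLC yields a clean, exact table", {
  cfg <- generator_config(seed = 5, noise_cv = 0)
  exp <- simulate_experiment(cfg)
  tab <- pair_measurements(exp$transients, exp$train)
  rec <- tab$records
  expect_equal(nrow(rec), 9)
  expect_equal(rec$par, exp$sequence$steps$par)
  bad <- c("light_fit_failed", "light_fit_unconverged", "dark1s_fit_failed",
           "dark1s_fit_unconverged", "missing_dark_1s", "derived_unavailable")
  expect_false(any(vapply(strsplit(rec$flags, ";"),
                          function(f) any(f %in% bad), TRUE)))
  # derived quantities match generator truth
  truth <- exp$truth[exp$truth$light_context == "actinic", ]
  expect_equal(rec$Y_NPQ, truth$Y_NPQ_truth, tolerance = 1e-5)
  expect_equal(rec$sigma_p, truth$sigma, tolerance = 1e-4)
  expect_equal(rec$FS, truth$FS_truth, tolerance = 1e-5)
  expect_equal(rec$tau1_light, truth$tau1, tolerance = 1e-3)
  expect_equal(rec$Y_PSII + rec$Y_NPQ + rec$Y_NO, rep(1, 9), tolerance = 1e-12)
})

test_that("pairing is order-invariant and isolates missing partners", {
  cfg <- generator_config(seed = 6, noise_cv = 0)
  exp <- simulate_experiment(cfg)
  tab <- pair_measurements(exp$transients, exp$train)
  set.seed(1)
  shuffled <- sample(exp$transients)
  tab2 <- pair_measurements(shuffled, exp$train)
  expect_equal(tab2$records, tab$records)
  # drop one dark_1s measurement: only its step is flagged
  drop_id <- tab$records$measurement_id[4]
  kept <- Filter(function(x) !(x$measurement_id == drop_id &&
                                 x$light_context == "dark_1s"),
                 exp$transients)
  tab3 <- pair_measurements(kept, exp$train)
  flagged <- grepl("missing_dark_1s", tab3$records$flags)
  expect_equal(which(flagged), 4L)
  expect_true(is.na(tab3$records$ETR[4]))
  expect_equal(tab3$records$ETR[-4], tab$records$ETR[-4], tolerance = 1e-9)
})

test_that("pair_measurements rejects malformed experiments", {
  expect_error(pair_measurements(list()), class = "frrf_protocol_mismatch")
  # no dark-adapted reference
  cfg <- generator_config(seed = 6, noise_cv = 0)
  exp <- simulate_experiment(cfg)
  no_ref <- Filter(function(x) x$light_context != "dark_adapted",
                   exp$transients)
  expect_error(pair_measurements(no_ref, exp$train),
               class = "frrf_protocol_mismatch")
})

test_that("upregulation index separates dynamic from static physiology", {
  # upregulation on: revisit ETR at 470 exceeds the first visit
  exp_up <- simulate_experiment(generator_config(seed = 9, noise_cv = 0,
                                                 upregulation = TRUE))
  up <- upregulation_index(pair_measurements(exp_up$transients, exp_up$train))
  expect_gt(up$ratio[up$par == 470], 1.1)
  # static physiology (DTT + no upregulation, noiseless): ratios of 1
  exp_null <- simulate_experiment(generator_config(seed = 9, noise_cv = 0,
                                                   upregulation = FALSE,
                                                   dtt_mode = TRUE))
  upn <- upregulation_index(pair_measurements(exp_null$transients,
                                              exp_null$train))
  expect_equal(upn$ratio, rep(1, nrow(upn)), tolerance = 1e-4)
  # NPQ retained at the final return to growth irradiance: ratio < 1
  expect_lt(up$ratio[up$par == 74], 1)
  # monotone ramp has no revisit
  mono <- simulate_experiment(generator_config(seed = 9, noise_cv = 0),
                              light_sequence(c(34, 74, 114, 300, 470), 30))
  expect_error(upregulation_index(pair_measurements(mono$transients,
                                                    mono$train)),
               class = "frrf_no_revisit")
})
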