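test_that("noiseless induction fits recover truth to high precision", {
  tr <- calibrated_train()
  st <- dark_state()
  fit <- fit_induction(simulate_induction(st, tr), tr)
  expect_true(fit$converged)
  expect_rel_equal(c(fit$F0_hat, fit$FM_hat, fit$sigma_hat, fit$rho_hat),
                   c(0.2, 1.0, 400, 0.3), 1e-6)
  expect_lt(fit$rss, fit$rss0)

  # across a parameter grid, including the rho = 0 boundary
  for (sigma in c(200, 600)) for (rho in c(0, 0.5)) for (FM in c(0.5, 1.0)) {
    sti <- dark_state(F0 = FM / 5, FM = FM, sigma = sigma, rho = rho)
    fi <- fit_induction(simulate_induction(sti, tr), tr)
    expect_rel_equal(c(fi$F0_hat, fi$FM_hat, fi$sigma_hat),
                     c(FM / 5, FM, sigma), 1e-4)
    expect_lt(abs(fi$rho_hat - rho), 1e-4)
  }
})

test_that("induction fit is invariant to uniform fluorescence rescaling", {
  tr <- calibrated_train()
  ind <- simulate_induction(dark_state(), tr)
  set.seed(3)
  ind <- add_noise(ind, 0.01)
  f1 <- fit_induction(ind, tr)
  ind_scaled <- ind
  ind_scaled$fluorescence <- ind$fluorescence * 1000
  f2 <- fit_induction(ind_scaled, tr)
  expect_equal(f2$F0_hat / f1$F0_hat, 1000, tolerance = 1e-6)
  expect_equal(f2$FM_hat / f1$FM_hat, 1000, tolerance = 1e-6)
  expect_equal(f2$sigma_hat, f1$sigma_hat, tolerance = 1e-6)
  expect_equal(f2$rho_hat, f1$rho_hat, tolerance = 1e-5)
})

test_that("degenerate and non-saturating inductions are handled as specified", {
  tr <- calibrated_train()
  flat <- frrf_transient(flashlet_times(tr), rep(0.5, 40), "induction")
  expect_error(fit_induction(flat, tr), class = "frrf_degenerate_input")
  # far-from-saturating rise: flagged and unconverged, not raised
  weak <- flashlet_train(dose_per_flashlet = calibrate_dose(400, 30, 0.98) / 20)
  fit <- fit_induction(simulate_induction(dark_state(), weak), weak)
  expect_false(fit$converged)
  expect_true("non_saturating" %in% fit$flags)
})

test_that("induction parameters are recovered under 1% noise", {
  tr <- calibrated_train()
  ind <- simulate_induction(dark_state(), tr)
  set.seed(101)
  fits <- t(replicate(40, {
    f <- fit_induction(add_noise(ind, 0.01), tr)
    c(f$sigma_hat, f$rho_hat)
  }))
  expect_lt(median(abs(fits[, 1] - 400) / 400), 0.05)
  expect_lt(median(abs(fits[, 2] - 0.3)), 0.05)
})

test_that("noiseless relaxation fits recover truth and canonicalize lifetimes", {
  tr <- calibrated_train()
  st <- dark_state()
  ifit <- fit_induction(simulate_induction(st, tr), tr)
  rel <- simulate_relaxation(st, C0 = ifit$C_end, times = relaxation_times())
  rfit <- fit_relaxation(rel, ifit)
  expect_true(rfit$converged)
  expect_rel_equal(c(rfit$tau1_hat, rfit$tau2_hat, rfit$alpha1_hat),
                   c(500, 5000, 0.7), 1e-6)
  expect_lte(rfit$tau1_hat, rfit$tau2_hat)
  expect_equal(rfit$alpha1_hat + rfit$alpha2_hat, 1)
  expect_lt(rfit$rss, rfit$rss0)
})

test_that("single-phase relaxation does not crash and reports equal lifetimes", {
  tr <- calibrated_train()
  st <- dark_state(tau1 = 1000, tau2 = 1000, alpha1 = 0.6)
  ifit <- fit_induction(simulate_induction(st, tr), tr)
  rel <- simulate_relaxation(st, C0 = ifit$C_end, times = relaxation_times())
  rfit <- fit_relaxation(rel, ifit)
  expect_true(rfit$converged)
  expect_equal(rfit$tau1_hat, rfit$tau2_hat)
  expect_equal(rfit$tau1_hat, 1000, tolerance = 0.05)
})

test_that("tau1 is recovered under 1% noise", {
  tr <- calibrated_train()
  st <- dark_state()
  ifit <- fit_induction(simulate_induction(st, tr), tr)
  rel <- simulate_relaxation(st, C0 = ifit$C_end, times = relaxation_times())
  set.seed(202)
  errs <- replicate(40, {
    rf <- fit_relaxation(add_noise(rel, 0.01), ifit)
    abs(rf$tau1_hat - 500) / 500
  })
  expect_lt(median(errs), 0.10)
})

test_that("restricted in-light fit recovers sigma from a partially closed start", {
  tr <- calibrated_train()
  st <- dark_state(F0 = 0.15, FM = 0.4, sigma = 300)
  ind <- simulate_induction(st, tr, C_init = 0.6, light_context = "actinic",
                            actinic_par = 470)
  fit <- fit_induction(ind, tr, rho_fix = 0.3, C_init = 0.6)
  expect_rel_equal(c(fit$F0_hat, fit$FM_hat, fit$sigma_hat),
                   c(0.15, 0.4, 300), 1e-5)
  expect_equal(fit$FS_hat, closure_to_fluorescence(0.6, 0.15, 0.4, 0.3),
               tolerance = 1e-6)
  # the relaxation toward the in-light steady state is fit with a floor
  C_end <- fit$C_end
  tt <- relaxation_times()
  C_rel <- 0.6 + (C_end - 0.6) * (0.7 * exp(-tt / 500) + 0.3 * exp(-tt / 5000))
  rel <- frrf_transient(tt, closure_to_fluorescence(C_rel, 0.15, 0.4, 0.3),
                        phase = "relaxation", light_context = "actinic",
                        actinic_par = 470)
  rfit <- fit_relaxation(rel, fit, C_floor = 0.6)
  expect_rel_equal(c(rfit$tau1_hat, rfit$tau2_hat), c(500, 5000), 1e-4)
})
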