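test_that("closure-to-fluorescence mapping has the right endpoints and shape", {
  for (rho in c(0, 0.3, 0.6)) {
    expect_equal(closure_to_fluorescence(0, 0.2, 1.0, rho), 0.2)
    expect_equal(closure_to_fluorescence(1, 0.2, 1.0, rho), 1.0)
  }
  # linear when rho = 0
  expect_equal(closure_to_fluorescence(0.5, 0.2, 1.0, 0), 0.6)
  # continuous and nondecreasing in C
  C <- seq(0, 1, length.out = 201)
  for (rho in c(0, 0.3, 0.6))
    expect_true(all(diff(closure_to_fluorescence(C, 0.2, 1.0, rho)) >= 0))
  # inverse round-trips
  Cr <- seq(0.01, 0.99, length.out = 25)
  for (rho in c(0, 0.3, 0.6)) {
    F <- closure_to_fluorescence(Cr, 0.2, 1.0, rho)
    expect_equal(closure_from_fluorescence(F, 0.2, 1.0, rho), Cr,
                 tolerance = 1e-12)
  }
  expect_error(closure_to_fluorescence(1.5, 0.2, 1, 0), class = "frrf_error")
})

test_that("flashlet train invariants and timestamps hold", {
  tr <- flashlet_train()
  expect_equal(tr$n_flashlets, 40L)
  ts <- flashlet_times(tr)
  expect_length(ts, 40)
  expect_true(all(diff(ts) > 0))
  expect_equal(ts, seq_len(40) * 2.2)
  expect_error(flashlet_train(n_flashlets = 0), class = "frrf_error")
  expect_error(flashlet_train(dose_per_flashlet = 0), class = "frrf_error")
  expect_error(photophys_state(F0 = 0.6, FM = 0.5), class = "frrf_error")
  expect_error(photophys_state(rho = 1), class = "frrf_error")
})

test_that("induction recursion matches the rho = 0 closed form", {
  # sigma * dose = 0.1 per flashlet: C_k = 1 - exp(-0.1 k)
  tr <- flashlet_train(dose_per_flashlet = 0.1 / 400)
  st <- dark_state(rho = 0)
  ind <- simulate_induction(st, tr)
  C <- attr(ind, "closure")
  k <- seq_len(40)
  expect_equal(C, 1 - exp(-0.1 * k), tolerance = 1e-12)
  expect_equal(C[2], 1 - exp(-0.2), tolerance = 1e-12)
  # C_init shifts the same closed form
  C2 <- attr(simulate_induction(st, tr, C_init = 0.5), "closure")
  expect_equal(C2, 1 - 0.5 * exp(-0.1 * k), tolerance = 1e-12)
})

test_that("induction traces are monotone, bounded, and sigmoidal under rho", {
  tr <- calibrated_train()
  for (rho in c(0, 0.3, 0.6)) {
    ind <- simulate_induction(dark_state(rho = rho), tr)
    y <- ind$fluorescence
    expect_true(all(diff(y) >= 0))
    expect_true(all(y >= 0.2 - 1e-12 & y <= 1 + 1e-12))
  }
  # higher rho depresses the early rise (more sigmoidal) at fixed dose
  first_point <- vapply(c(0, 0.3, 0.6), function(rho)
    simulate_induction(dark_state(rho = rho), tr)$fluorescence[1], 0)
  expect_true(all(diff(first_point) < 0))
  # vanishing cross section: flat trace at F0
  flat <- simulate_induction(dark_state(sigma = 1e-9), tr)
  expect_equal(flat$fluorescence, rep(0.2, 40), tolerance = 1e-6)
})

test_that("per-flashlet recursion agrees with brute-force substep integration", {
  dose <- calibrate_dose(400, 30, 0.98)
  tr <- flashlet_train(dose_per_flashlet = dose)
  for (sigma in c(200, 400, 600)) for (rho in c(0, 0.3, 0.6)) {
    Cd <- attr(simulate_induction(dark_state(sigma = sigma, rho = rho), tr),
               "closure")
    Co <- oracle_induction_closure(sigma, rho, dose, 40)
    expect_rel_equal(Cd, Co, 1e-4)
  }
})

test_that("inter-flashlet relaxation lowers the trace when enabled", {
  tr <- calibrated_train()
  st <- dark_state()
  base <- simulate_induction(st, tr)$fluorescence
  relaxed <- simulate_induction(st, tr, relax_between_flashlets = TRUE)$fluorescence
  expect_true(all(relaxed <= base + 1e-12))
  expect_lt(relaxed[40], base[40])
})

test_that("relaxation follows the biexponential closed forms", {
  st <- dark_state(rho = 0)
  tt <- relaxation_times(60, 1, 2e5)
  rel <- simulate_relaxation(st, C0 = 0.9, times = tt)
  expect_true(all(diff(rel$fluorescence) < 0))
  # t -> infinity: back to F0 (t > 20 tau2)
  expect_lt(abs(rel$fluorescence[60] - 0.2), 1e-6 * 0.8)
  # single phase at alpha2 = 0, rho = 0: F(tau1) = F0 + (FM - F0) C0 / e
  st1 <- dark_state(rho = 0, alpha1 = 1)
  r1 <- simulate_relaxation(st1, C0 = 0.9, times = c(250, 500, 1000, 2000))
  expect_equal(r1$fluorescence[2], 0.2 + 0.8 * 0.9 / exp(1), tolerance = 1e-12)
  # t = 0 initial condition
  r0 <- simulate_relaxation(st, C0 = 0.8, times = c(0, 10, 20, 30))
  expect_equal(r0$fluorescence[1], closure_to_fluorescence(0.8, 0.2, 1, 0))
})

test_that("relaxation is invariant under amplitude-lifetime label swap", {
  tt <- relaxation_times()
  a <- simulate_relaxation(dark_state(tau1 = 500, tau2 = 5000, alpha1 = 0.7),
                           C0 = 0.95, times = tt)
  # photophys_state enforces tau1 <= tau2, so build the swapped curve directly
  C_swap <- 0.95 * (0.3 * exp(-tt / 5000) + 0.7 * exp(-tt / 500))
  b <- closure_to_fluorescence(C_swap, 0.2, 1.0, 0.3)
  expect_equal(a$fluorescence, b, tolerance = 1e-14)
})

test_that("dose calibration hits its closure target and scales correctly", {
  d <- calibrate_dose(400, 30, 0.98)
  expect_equal(d, -log(0.02) / (400 * 30), tolerance = 1e-14)
  C <- attr(simulate_induction(dark_state(rho = 0),
                               flashlet_train(dose_per_flashlet = d)),
            "closure")
  expect_equal(C[30], 0.98, tolerance = 1e-12)
  # scaling symmetry and small-closure limit
  expect_equal(calibrate_dose(800, 30, 0.98), d / 2, tolerance = 1e-14)
  expect_lt(calibrate_dose(400, 30, 1e-9), 1e-12)
})

test_that("transient constructor validates its contract", {
  expect_error(frrf_transient(c(1, 2, 2, 3), c(1, 1, 1, 1), "induction"),
               class = "frrf_error")
  expect_error(frrf_transient(1:3, c(1, 1, 1), "induction"),
               class = "frrf_error")
  expect_error(frrf_transient(1:4, c(1, 1, 1, -1), "induction"),
               class = "frrf_error")
  expect_error(frrf_transient(1:4, rep(1, 4), "induction",
                              light_context = "dark_1s", actinic_par = 100),
               class = "frrf_error")
})
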