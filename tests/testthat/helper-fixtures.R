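# shared fixtures: a calibrated default train and a canonical dark state
calibrated_train <- function(sigma_ref = 400) {
  flashlet_train(dose_per_flashlet = calibrate_dose(sigma_ref, 30, 0.98))
}

dark_state <- function(...) {
  args <- utils::modifyList(list(F0 = 0.2, FM = 1.0, sigma = 400, rho = 0.3,
                                 tau1 = 500, tau2 = 5000, alpha1 = 0.7),
                            list(...))
  do.call(photophys_state, args)
}

# multiplicative noise applied to a transient, local RNG
add_noise <- function(transient, cv) {
  transient$fluorescence <-
    pmax(transient$fluorescence *
           (1 + stats::rnorm(length(transient$fluorescence), 0, cv)), 0)
  transient
}

# brute-force induction oracle: 1000 uniform Euler substeps per flashlet
oracle_induction_closure <- function(sigma, rho, dose, n, n_sub = 1000) {
  C <- numeric(n)
  c_cur <- 0
  dE <- dose / n_sub
  for (k in seq_len(n)) {
    for (s in seq_len(n_sub))
      c_cur <- c_cur + sigma * dE * (1 - c_cur) / (1 - rho * c_cur)
    C[k] <- min(c_cur, 1)
  }
  C
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
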