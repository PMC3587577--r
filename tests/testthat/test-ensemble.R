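test_that("relative quantum yield is the fluorescence-on-absorbance slope", {
  s <- fluor_abs_series(0, c(0.01, 0.02, 0.03), c(10, 20, 30))
  qy <- relative_quantum_yield(s)
  expect_equal(qy$phi, 1000)
  expect_equal(qy$intercept, 0, tolerance = 1e-10)
  s2 <- fluor_abs_series(0, c(0.01, 0.02, 0.03), c(5, 10, 15))
  expect_equal(relative_quantum_yield(s2)$phi, 500)
  expect_equal(relative_quantum_yield(s2, through_origin = TRUE)$phi, 500)
  expect_error(relative_quantum_yield(
    fluor_abs_series(0, c(0.02, 0.02), c(10, 11))))
  expect_error(fluor_abs_series(0, 0.01, 10))          # one point
  expect_error(fluor_abs_series(0, c(0.5, 0.6), c(1, 2)))  # inner-filter regime
})

test_that("slope estimator and its standard error are calibrated", {
  # with 3 points and a free intercept the residual variance has a single
  # degree of freedom, so (phi_hat - phi)/se is Student t with 1 df:
  # the 3-SE interval covers the truth with probability ~0.80, not the
  # Gaussian 0.997
  set.seed(21)
  phi_true <- 1000
  A <- c(0.008, 0.012, 0.017)
  res <- t(vapply(seq_len(1000), function(i) {
    Fl <- phi_true * A * (1 + rnorm(3, 0, 0.01))
    qy <- relative_quantum_yield(fluor_abs_series(0, A, Fl))
    c(hit = abs(qy$phi - phi_true) <= 3 * qy$se_phi, phi = qy$phi)
  }, numeric(2)))
  expect_gt(mean(res[, "hit"]), 2 * stats::pt(3, df = 1) - 1 - 0.05)
  expect_lt(mean(res[, "hit"]), 2 * stats::pt(3, df = 1) - 1 + 0.05)
  # the point estimate itself is unbiased to Monte-Carlo precision
  expect_lt(abs(mean(res[, "phi"]) / phi_true - 1), 0.005)
})

test_that("build_quench_curve forms ratios with propagated uncertainties", {
  mk <- function(cq, phi) fluor_abs_series(cq, c(0.01, 0.02, 0.03),
                                           phi * c(0.01, 0.02, 0.03))
  # identical series give all ratios 1
  cv <- build_quench_curve(list(mk(0, 800), mk(1e-5, 800), mk(2e-5, 800)))
  expect_equal(cv$ratio, rep(1, 3), tolerance = 1e-9)
  # phi0 = 1000, phi(20 uM) = 55 -> ratio 18.18
  cv2 <- build_quench_curve(list(mk(0, 1000), mk(2e-5, 55)))
  expect_equal(cv2$ratio[cv2$conc == 2e-5], 1000 / 55, tolerance = 1e-9)
  # missing zero-concentration series is an error
  expect_error(build_quench_curve(list(mk(1e-6, 900), mk(2e-6, 800))),
               "quencher_conc = 0")
})

test_that("ratio uncertainty follows first-order error propagation", {
  # sqrt((se0/phi)^2 + (phi0*se/phi^2)^2) with phi0 = 1000 +/- 10, phi = 500 +/- 10
  phi0 <- 1000; se0 <- 10; phi <- 500; se <- 10
  expect_equal(sqrt((se0 / phi)^2 + (phi0 * se / phi^2)^2), 0.04472136,
               tolerance = 1e-6)
  # and the pipeline reproduces it: build a synthetic pair whose slope SEs
  # we can read back, then check sigma against the same formula
  set.seed(31)
  A <- c(0.008, 0.012, 0.016, 0.02)
  s0 <- fluor_abs_series(0, A, 1000 * A + rnorm(4, 0, 0.02))
  s1 <- fluor_abs_series(1e-5, A, 500 * A + rnorm(4, 0, 0.02))
  q0 <- relative_quantum_yield(s0); q1 <- relative_quantum_yield(s1)
  cv <- build_quench_curve(list(s0, s1))
  expected <- sqrt((q0$se_phi / q1$phi)^2 + (q0$phi * q1$se_phi / q1$phi^2)^2)
  expect_equal(cv$sigma[cv$conc == 1e-5], expected, tolerance = 1e-9)
})

test_that("two-state fit recovers exact parameters from noiseless data", {
  cv <- noiseless_curve()
  ft <- fit_two_state(cv)
  expect_true(ft$converged)
  expect_equal(ft$logK, 6.95, tolerance = 1e-4)
  expect_equal(ft$f, 0.05, tolerance = 1e-4)
  expect_lt(ft$chi2_red, 1e-6)
  expect_error(fit_two_state(cv[1:3, ]))
  expect_error(fit_two_state(cv, use_precise = TRUE))  # L0 missing
})

test_that("two-state fit on Stern-Volmer data pins f at its lower bound", {
  cc <- default_conc_grid()
  r <- stern_volmer_ratio(1e5, cc)
  cv <- quench_curve(cc, r, pmax(0.02 * r, 1e-8))
  ft <- fit_two_state(cv)
  sv <- fit_stern_volmer(cv)
  # the two-state model nests the linear law as f -> 0
  expect_lte(ft$f, 1e-4)
  expect_equal(sv$ksv, 1e5, tolerance = 1e-9)
  expect_lt(abs(ft$chi2_red - sv$chi2_red), 1e-6 + 2 * sv$chi2_red)
})

test_that("Stern-Volmer fit recovers an exact line and rejects degenerate input", {
  cc <- default_conc_grid()
  cv <- quench_curve(cc, 1 + 1e5 * cc, rep(0.02, length(cc)))
  expect_equal(fit_stern_volmer(cv)$ksv, 1e5, tolerance = 1e-9)
  expect_error(quench_curve(numeric(0), numeric(0), numeric(0)))
  expect_error(fit_stern_volmer(quench_curve(c(0, 1e-6), c(1, 1.1),
                                             c(0.01, 0.01))))
})

test_that("model comparison ranks the generating model first on curved data", {
  cv <- gen_quench_curve(tmr_params(), seed = 7)
  cmp <- compare_models(cv)
  expect_equal(cmp$ranking[1], "approx_two_state")
  # and on truly linear data the two models are statistically tied
  set.seed(8)
  cc <- default_conc_grid()
  mu <- stern_volmer_ratio(8e4, cc)
  r <- mu * (1 + rnorm(length(cc), 0, 0.02)); r[1] <- 1
  cvl <- quench_curve(cc, r, 0.02 * mu)
  cmpl <- compare_models(cvl)
  expect_lt(max(cmpl$chi2_red) / min(cmpl$chi2_red), 2)
  expect_error(compare_models(quench_curve(0, 1, 0.01)))
})

test_that("precise-model fit removes the approximate-fit bias at high K * L0", {
  # data generated from the exact mass-balance model at L0 = 0.5 uM and
  # K = 10^7.6: probe depletion of the quencher biases the approximate fit
  p <- two_state_params(logK = 7.6, f = 0.1)
  L0 <- 0.5e-6
  cv <- gen_quench_curve(p, noise_frac = 0, seed = 1, use_precise = TRUE,
                         L0 = L0)
  fa <- fit_two_state(cv)
  fp <- fit_two_state(cv, use_precise = TRUE, L0 = L0)
  expect_equal(fp$logK, 7.6, tolerance = 1e-3)
  expect_equal(fp$f, 0.1, tolerance = 1e-3)
  expect_gt(abs(fa$logK - 7.6), 10 * abs(fp$logK - 7.6))
})
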