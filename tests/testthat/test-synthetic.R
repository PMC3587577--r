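test_that("generators are bit-reproducible for a fixed seed and record metadata", {
  p <- tmr_params()
  a <- gen_quench_curve(p, seed = 5); b <- gen_quench_curve(p, seed = 5)
  expect_identical(a$ratio, b$ratio)
  expect_equal(attr(a, "meta")$seed, 5)
  t1 <- gen_blinking_trace(blinking_model(seed = 9))
  t2 <- gen_blinking_trace(blinking_model(seed = 9))
  expect_identical(t1$counts, t2$counts)
  expect_equal(attr(t1, "meta")$rate_bright, 40)
  s1 <- gen_ensemble_titration(p, seed = 3)
  s2 <- gen_ensemble_titration(p, seed = 3)
  expect_identical(s1[[5]]$fluorescence, s2[[5]]$fluorescence)
  expect_false(identical(s1[[5]]$fluorescence,
                         gen_ensemble_titration(p, seed = 4)[[5]]$fluorescence))
})

test_that("noiseless ensemble titration round-trips through the slope pipeline", {
  p <- two_state_params(logK = 6.5, f = 0.2)
  series <- gen_ensemble_titration(p, noise_frac = 0, seed = 1)
  cv <- build_quench_curve(series)
  expect_equal(cv$ratio, approx_ratio(p, cv$conc), tolerance = 1e-9)
  # with f = 1 the complex is as bright as the free probe: nothing changes
  series1 <- gen_ensemble_titration(two_state_params(logK = 6.5, f = 1),
                                    noise_frac = 0, seed = 1)
  cv1 <- build_quench_curve(series1)
  expect_equal(cv1$ratio, rep(1, nrow(cv1)), tolerance = 1e-9)
})

test_that("absorbance generator respects the binding limits", {
  # stoichiometric limit: absorbance saturates at A0 + delta_eps * d * L0
  t_sat <- gen_absorbance_titration(K = 1e12, L0 = 0.5e-6, delta_eps = 5e4,
                                    d = 0.3, A0 = 0.05,
                                    metal_grid = seq(1e-5, 5e-5, 1e-5),
                                    noise_abs = 0, seed = 1)
  expect_equal(max(t_sat$absorbance), 0.05 + 5e4 * 0.3 * 0.5e-6,
               tolerance = 1e-6)
  # BH validity regime (metal >> L0, K*metal << 1): transform exactly linear
  t_bh <- gen_absorbance_titration(K = 1e3, L0 = 1e-9, delta_eps = 5e7,
                                   metal_grid = seq(1e-6, 5e-5,
                                                    length.out = 8),
                                   noise_abs = 0, seed = 1)
  tp <- bh_transform(t_bh)
  expect_gt(summary(stats::lm(y ~ x, tp))$r.squared, 1 - 1e-9)
})

test_that("blinking traces follow the two-state Markov statistics", {
  # k_on = 0: bright-only until bleach
  m <- blinking_model(k_on = 0, k_off = 1, bleach_rate = 0, duration = 5,
                      seed = 2)
  tr <- gen_blinking_trace(m)
  expect_equal(attr(tr, "meta")$occ_bright, 1)
  expect_gt(mean(tr$counts), 35)  # Poisson(40) bins only
  # stationary occupancy of the bright state is k_off / (k_on + k_off)
  occs <- vapply(1:20, function(i) {
    tr <- gen_blinking_trace(blinking_model(k_on = 1, k_off = 3,
                                            bleach_rate = 0, duration = 60,
                                            seed = 100 + i))
    attr(tr, "meta")$occ_bright
  }, 0)
  # dwell-limited Monte-Carlo sd: about sqrt(p(1-p)/n_cycles)
  expect_lt(abs(mean(occs) - 0.75), 3 * sd(occs) / sqrt(length(occs)))
  expect_error(blinking_model(duration = 0))
  expect_error(blinking_model(rate_bg = 50))  # bg above dim level
})

test_that("indistinguishable dim and bright states give a unimodal signal", {
  m <- blinking_model(rate_dim = 40, rate_bright = 40, rate_bg = 2,
                      bleach_rate = 0, duration = 10, seed = 3)
  tr <- gen_blinking_trace(m)
  h <- accumulate_histogram(tr)
  # all mass in one Poisson(40)-shaped mode
  mids_occ <- h$mids[h$occupancy > 0]
  expect_gt(min(mids_occ), 15)
  expect_lt(diff(range(mids_occ)), 60)
})

test_that("precise-model generation exposes the approximate-fit bias at high K", {
  p <- two_state_params(logK = 7.6, f = 0.1)
  series <- gen_ensemble_titration(p, noise_frac = 0, seed = 1,
                                   use_precise = TRUE)
  cv <- build_quench_curve(series)
  fa <- fit_two_state(cv)
  expect_gt(abs(fa$logK - 7.6), 0.01)
})

test_that("gen_spectra builds band spectra with the stated structure", {
  sp <- gen_spectra(data.frame(center = 580, width = 15, amplitude = 2),
                    "emission")
  expect_equal(sp$wavelength[which.max(sp$value)], 580)
  expect_equal(max(sp$value), 2, tolerance = 1e-6)
  expect_error(gen_spectra(data.frame(center = 580, width = 0,
                                      amplitude = 1), "emission"))
})
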