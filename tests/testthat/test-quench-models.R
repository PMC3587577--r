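test_that("Stern-Volmer ratio is linear with the expected limits", {
  expect_equal(stern_volmer_ratio(1e5, 0), 1)
  expect_equal(stern_volmer_ratio(0, 2e-5), 1)
  expect_equal(stern_volmer_ratio(1e5, 2e-5), 3.0)
  expect_equal(stern_volmer_ratio(1e5, c(0, 1e-5, 2e-5)), c(1, 2, 3))
  expect_error(stern_volmer_ratio(-1, 1e-6))
  expect_error(stern_volmer_ratio(1e5, -1e-6))
})

test_that("two_state_params validates its fields", {
  p <- two_state_params(logK = 6.95, f = 0.05)
  expect_equal(p$K, 10^6.95)
  expect_equal(p$logK, 6.95)
  expect_error(two_state_params(K = -1, f = 0.5))
  expect_error(two_state_params(K = 1e6, f = 1.5))
  expect_error(two_state_params(K = 1e6, logK = 6, f = 0.5))
  expect_error(two_state_params(f = 0.5))
})

test_that("approximate two-state ratio matches hand-evaluated values and limits", {
  p <- two_state_params(logK = 6.95, f = 0.05)
  expect_equal(approx_ratio(p, 0), 1)
  expect_equal(approx_ratio(two_state_params(K = 1e7, f = 1), c(0, 1e-6, 1e-4)),
               rep(1, 3))
  # (1 + 178.25) / (1 + 0.05 * 178.25), evaluated independently
  expect_equal(approx_ratio(p, 2e-5), 18.08323, tolerance = 1e-6)
  # f = 0 reduces to the static Stern-Volmer form 1 + K c
  p0 <- two_state_params(K = 1e5, f = 0)
  expect_equal(approx_ratio(p0, 2e-5), stern_volmer_ratio(1e5, 2e-5))
  expect_error(approx_ratio(p, -1e-6))
})

test_that("approx_ratio is nondecreasing in c and saturates at 1/f", {
  for (logK in c(4.5, 6, 7)) for (f in c(0.05, 0.3, 0.8)) {
    p <- two_state_params(logK = logK, f = f)
    cc <- seq(0, 1e4 / p$K, length.out = 200)
    r <- approx_ratio(p, cc)
    expect_true(all(diff(r) >= 0))
    expect_true(all(r <= 1 / f + 1e-12))
    expect_equal(r[length(r)], 1 / f, tolerance = 5e-3)
  }
})

test_that("solve_equilibrium returns the physical root of the mass balance", {
  expect_equal(solve_equilibrium(1e6, 0, 1e-5)$ML, 0)
  expect_equal(solve_equilibrium(1e6, 1e-5, 0)$ML, 0)
  # equimolar case has the closed form L0 * (3 - sqrt(5)) / 2 at K L0 = 1
  expect_equal(solve_equilibrium(1e6, 1e-6, 1e-6)$ML, 1e-6 * (3 - sqrt(5)) / 2,
               tolerance = 1e-12)
  # strong-binding limit: all probe bound
  expect_equal(solve_equilibrium(1e12, 1e-6, 2e-5)$ML, 1e-6, tolerance = 1e-5)
  expect_error(solve_equilibrium(-1, 1e-6, 1e-6))
  expect_error(solve_equilibrium(1e6, -1e-6, 1e-6))
})

test_that("solve_equilibrium satisfies the mass-balance residual and matches bisection", {
  set.seed(11)
  n <- 300
  K <- 10^runif(n, 2, 12)
  L0 <- 10^runif(n, -9, -4)
  M0 <- 10^runif(n, -9, -4)
  for (i in seq_len(n)) {
    ml <- solve_equilibrium(K[i], L0[i], M0[i])$ML
    expect_lte(ml, min(L0[i], M0[i]) * (1 + 1e-12))
    expect_gte(ml, 0)
    # residual of K (L0 - ML)(M0 - ML) = ML; the tolerance allows for
    # round-off in evaluating the residual itself (the (L0 - ML) factor
    # cancels catastrophically in the strong-binding limit)
    resid <- abs(K[i] * (L0[i] - ml) * (M0[i] - ml) - ml)
    expect_lt(resid, 1e-9 * ml + 16 * .Machine$double.eps * K[i] * L0[i] * M0[i])
    expect_equal(ml, bisect_ml(K[i], L0[i], M0[i]), tolerance = 1e-9)
  }
})

test_that("precise ratio agrees with the bisection-oracle value and its limits", {
  p <- two_state_params(K = 1e6, f = 0.05)
  expect_equal(precise_ratio(p, 1e-6, 1e-6), 1 / (1 - 0.95 * (3 - sqrt(5)) / 2),
               tolerance = 1e-9)
  expect_equal(precise_ratio(two_state_params(K = 1e7, f = 1), 1e-6, 1e-5), 1)
  # dilute-probe limit reduces to the approximate model
  expect_equal(precise_ratio(p, 1e-12, 2e-5), approx_ratio(p, 2e-5),
               tolerance = 1e-6)
  expect_error(precise_ratio(p, 0, 1e-5))
})

test_that("depletion only reduces quenching: precise <= approximate", {
  grid <- expand.grid(logK = c(5, 6.5, 8), f = c(0.05, 0.4),
                      L0 = c(1e-7, 5e-7, 2e-6), M0 = c(1e-6, 5e-6, 2e-5))
  for (i in seq_len(nrow(grid))) {
    p <- two_state_params(logK = grid$logK[i], f = grid$f[i])
    expect_lte(precise_ratio(p, grid$L0[i], grid$M0[i]),
               approx_ratio(p, grid$M0[i]) + 1e-12)
  }
})

test_that("precise and approximate models agree when K*L0 is small", {
  # the regime in which the two models differ by less than experimental error
  for (logK in c(4.5, 5.5, 6.5)) {
    K <- 10^logK
    L0 <- 1e-4 / K   # K * L0 = 1e-4 < 1e-3
    p <- two_state_params(K = K, f = 0.1)
    M0 <- seq(0, 20e-6, length.out = 21)[-1]
    rel <- abs(precise_ratio(p, L0, M0) / approx_ratio(p, M0) - 1)
    expect_true(all(rel < 1e-3))
  }
})
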