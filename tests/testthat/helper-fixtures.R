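# shared fixtures for the test suite; everything is generated in code

tmr_params <- function() two_state_params(logK = 6.95, f = 0.05)

# bisection oracle for the 1:1 mass-balance equation, independent of the
# closed-form quadratic used by solve_equilibrium
bisect_ml <- function(K, L0, M0, tol = 1e-15) {
  if (L0 == 0 || M0 == 0) return(0)
  g <- function(ml) K * (L0 - ml) * (M0 - ml) - ml
  stats::uniroot(g, c(0, min(L0, M0)), tol = tol * min(L0, M0))$root
}

# a clean noiseless curve on the standard grid
noiseless_curve <- function(params = tmr_params()) {
  gen_quench_curve(params, noise_frac = 0, seed = 1)
}
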