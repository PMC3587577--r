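#' Default quencher concentration grid
#'
#' 21 evenly spaced quencher concentrations from 0 to 20 uM, the titration
#' design of the ensemble experiments.
#'
#' @return Concentrations in mol/L.
#' @export
default_conc_grid <- function() seq(0, 20e-6, length.out = 21)

#' Simulate an ensemble fluorescence/absorbance titration
#'
#' Generates, for every quencher concentration, a [fluor_abs_series] over
#' several probe concentrations.  Absorbance is proportional to the probe
#' concentration and independent of the quencher (the probe's absorption
#' band is only very weakly perturbed by metal binding); fluorescence is
#' `absorbance * phi0 / ratio(c)` times multiplicative Gaussian noise, where
#' the quenching ratio comes from the approximate two-state model or, with
#' `use_precise = TRUE`, the exact mass-balance model evaluated at each
#' probe concentration.
#'
#' @param params A [two_state_params] object (the ground truth).
#' @param conc_grid Quencher concentrations, mol/L.  Default
#'   [default_conc_grid()].
#' @param probe_concs Probe concentrations, mol/L.  Default
#'   `c(0.34, 0.47, 0.68) * 1e-6`, the sub-micromolar range where
#'   re-absorption is negligible.
#' @param noise_frac Standard deviation of the multiplicative Gaussian noise
#'   on fluorescence (photometric noise).  Default 0.02.
#' @param seed Integer seed; the generator is bit-reproducible given it.
#' @param phi0 Unquenched relative quantum yield (slope units), arbitrary.
#' @param abs_per_molar Absorbance per mol/L of probe (extinction times path
#'   length).  Default 2.5e4, giving absorbances of about 0.01-0.02.
#' @param use_precise Use [precise_ratio] (per probe concentration) instead
#'   of [approx_ratio].
#' @return List of [fluor_abs_series] with attribute `meta` recording the
#'   seed and parameters.
#' @export
gen_ensemble_titration <- function(params, conc_grid = default_conc_grid(),
                                   probe_concs = c(0.34, 0.47, 0.68) * 1e-6,
                                   noise_frac = 0.02, seed = 1,
                                   phi0 = 1000, abs_per_molar = 2.5e4,
                                   use_precise = FALSE) {
  stopifnot(inherits(params, "two_state_params"))
  if (!length(conc_grid) || !length(probe_concs)) stop("empty grids")
  if (noise_frac < 0) stop("'noise_frac' must be non-negative")
  set.seed(as.integer(seed))
  out <- lapply(conc_grid, function(cq) {
    A <- abs_per_molar * probe_concs
    ratio <- if (use_precise)
      vapply(probe_concs, function(L0) precise_ratio(params, L0, cq), 0)
    else rep_len(approx_ratio(params, cq), length(probe_concs))
    Fl <- A * phi0 / ratio * (1 + stats::rnorm(length(A), 0, noise_frac))
    fluor_abs_series(cq, A, Fl)
  })
  attr(out, "meta") <- list(seed = seed, logK = params$logK, f = params$f,
                            noise_frac = noise_frac, phi0 = phi0,
                            probe_concs = probe_concs,
                            use_precise = use_precise)
  out
}

#' Simulate a quenching-ratio curve directly
#'
#' The curve-level form of the recovery protocol: quenching ratios are the
#' model values times multiplicative Gaussian noise, with per-point sigma
#' equal to `noise_frac` times the model value (the noise model is known to
#' the simulator, so the weights handed to the fitters are exact).  The
#' zero-concentration point is fixed at ratio 1, mirroring
#' [build_quench_curve].
#'
#' @param params A [two_state_params] object.
#' @param conc_grid Quencher concentrations, mol/L.
#' @param noise_frac Multiplicative noise level.  Default 0.02.
#' @param seed Integer seed.
#' @param use_precise,L0 Generate from the exact mass-balance model at probe
#'   concentration `L0` instead of the approximate model.
#' @return A [quench_curve] with attribute `meta`.
#' @export
gen_quench_curve <- function(params, conc_grid = default_conc_grid(),
                             noise_frac = 0.02, seed = 1,
                             use_precise = FALSE, L0 = NULL) {
  stopifnot(inherits(params, "two_state_params"))
  if (noise_frac < 0) stop("'noise_frac' must be non-negative")
  set.seed(as.integer(seed))
  mu <- if (use_precise) precise_ratio(params, L0, conc_grid)
        else approx_ratio(params, conc_grid)
  eps <- stats::rnorm(length(mu), 0, noise_frac)
  ratio <- mu * (1 + eps)
  # sigma floor keeps weights finite for noiseless (validation) curves
  sigma <- pmax(noise_frac * mu, 1e-8)
  ratio[conc_grid == 0] <- 1
  cv <- quench_curve(conc_grid, ratio, sigma)
  attr(cv, "meta") <- list(seed = seed, logK = params$logK, f = params$f,
                           noise_frac = noise_frac, use_precise = use_precise,
                           L0 = L0)
  cv
}

#' Simulate an absorbance titration for Benesi-Hildebrand analysis
#'
#' `A(M0) = A0 + delta_eps * d * ML(K, L0, M0)` with `ML` from the full 1:1
#' mass balance ([solve_equilibrium]), not the excess-metal approximation,
#' plus additive Gaussian noise.  In the excess-metal regime the BH
#' transform of this data is linear; at metal concentrations comparable to
#' the probe concentration it bends away from the line, which is the
#' qualitative low-concentration deviation seen in real titrations.
#'
#' @param K Association constant, 1/(mol/L).
#' @param L0 Total probe concentration, mol/L.  Default 0.5e-6.
#' @param delta_eps Extinction-coefficient difference between complex and
#'   free probe at the evaluation wavelength, 1/(mol/L)/cm.  Default 5e4.
#' @param d Path length, cm.  Default 0.3 (a short-path cuvette).
#' @param A0 Baseline absorbance at zero metal.  Default 0.05.
#' @param metal_grid Metal concentrations, mol/L.  Default 10 points from 1
#'   to 50 uM.
#' @param noise_abs Additive absorbance noise sd.  Default 0.
#' @param seed Integer seed.
#' @return An [absorbance_titration] with attribute `meta`.
#' @export
gen_absorbance_titration <- function(K, L0 = 0.5e-6, delta_eps = 5e4,
                                     d = 0.3, A0 = 0.05,
                                     metal_grid = seq(1e-6, 50e-6,
                                                      length.out = 10),
                                     noise_abs = 0, seed = 1) {
  if (noise_abs < 0) stop("'noise_abs' must be non-negative")
  set.seed(as.integer(seed))
  ML <- solve_equilibrium(K, L0, metal_grid)$ML
  A <- A0 + delta_eps * d * ML + stats::rnorm(length(metal_grid), 0, noise_abs)
  titr <- absorbance_titration(metal_grid, A, L0 = L0, d = d, A0 = A0)
  attr(titr, "meta") <- list(seed = seed, logK = log10(K),
                             delta_eps = delta_eps, noise_abs = noise_abs)
  titr
}

#' Blinking-model parameters for single-molecule trace simulation
#'
#' Two emissive states (bright = free probe, dim = metal-bound) switching as
#' a continuous-time Markov chain, with Poisson photon counting per time bin
#' and single-step photobleaching to a background level.  Defaults emulate
#' low-excitation-power confocal traces of an immobilised dye--bipy--DNA
#' probe at 0.1 uM quencher: 1 ms bins over 30 s, bright state about 40
#' counts/bin, background 2 counts/bin, dim level set by the target
#' dim-to-bright brightness ratio, second-scale switching and an exponential
#' bleach time of mean 20 s.
#'
#' @param k_on Effective binding rate bright -> dim at the set quencher
#'   concentration, 1/s.
#' @param k_off Dissociation rate dim -> bright, 1/s.
#' @param rate_bright,rate_dim,rate_bg Expected counts per bin in each
#'   state; must satisfy `rate_bg <= rate_dim <= rate_bright`.  `rate_dim`
#'   defaults to the level giving a background-corrected dim/bright ratio
#'   `f_true`.
#' @param f_true Target `(rate_dim - rate_bg) / (rate_bright - rate_bg)`
#'   used only to default `rate_dim`.  Default 0.18.
#' @param bleach_rate Photobleaching rate, 1/s (0 = no bleaching).  Default
#'   1/20.
#' @param duration Trace length, s.  Default 30.
#' @param bin_width Bin width, s.  Default 1e-3.
#' @param seed Integer seed.
#' @return An object of class `blinking_model`.
#' @export
blinking_model <- function(k_on = 2, k_off = 2, rate_bright = 40,
                           rate_dim = NULL, rate_bg = 2, f_true = 0.18,
                           bleach_rate = 1/20, duration = 30,
                           bin_width = 1e-3, seed = 1) {
  if (is.null(rate_dim)) rate_dim <- rate_bg + f_true * (rate_bright - rate_bg)
  if (any(c(k_on, k_off, rate_bright, rate_dim, rate_bg, bleach_rate) < 0))
    stop("rates must be non-negative")
  if (!(rate_bg <= rate_dim && rate_dim <= rate_bright))
    stop("need rate_bg <= rate_dim <= rate_bright")
  if (duration <= 0) stop("'duration' must be positive")
  if (bin_width <= 0 || bin_width > duration)
    stop("'bin_width' must be positive and no longer than the trace")
  structure(list(k_on = k_on, k_off = k_off, rate_bright = rate_bright,
                 rate_dim = rate_dim, rate_bg = rate_bg,
                 bleach_rate = bleach_rate, duration = duration,
                 bin_width = bin_width, seed = as.integer(seed)),
            class = "blinking_model")
}

#' Simulate a single-molecule blinking trace
#'
#' Simulates the two-state Markov chain of [blinking_model] (exponential
#' dwell times `1/k_on` in the bright and `1/k_off` in the dim state,
#' started from the stationary distribution), draws an exponential bleach
#' time after which the emitter sits at the background level, computes each
#' bin's expected count as the time-weighted mixture of the state rates
#' within the bin (correct even when dwell times are comparable to the bin
#' width), and draws Poisson counts.
#'
#' @param model A [blinking_model].
#' @return A [photon_trace] with attribute `meta` (seed, parameters, bleach
#'   time, bright-state occupancy before bleaching).
#' @export
gen_blinking_trace <- function(model) {
  stopifnot(inherits(model, "blinking_model"))
  set.seed(model$seed)
  t_bleach <- if (model$bleach_rate > 0) stats::rexp(1, model$bleach_rate) else Inf
  t_active <- min(t_bleach, model$duration)
  # stationary start: P(bright) = k_off / (k_on + k_off)
  p_bright <- if (model$k_on + model$k_off > 0)
    model$k_off / (model$k_on + model$k_off) else 1
  state <- if (stats::runif(1) < p_bright) "bright" else "dim"
  bounds <- 0; rates <- numeric(0)
  t <- 0
  while (t < t_active) {
    leave <- if (state == "bright") model$k_on else model$k_off
    dwell <- if (leave > 0) stats::rexp(1, leave) else Inf
    rates <- c(rates, if (state == "bright") model$rate_bright else model$rate_dim)
    t <- min(t + dwell, t_active)
    bounds <- c(bounds, t)
    state <- if (state == "bright") "dim" else "bright"
  }
  if (t_active < model$duration) {
    rates <- c(rates, model$rate_bg)
    bounds <- c(bounds, model$duration)
  }
  if (length(rates) == 0) { rates <- model$rate_bg; bounds <- c(0, model$duration) }
  # cumulative expected counts at segment boundaries, then at bin edges
  lam_rate <- rates / model$bin_width            # counts per second
  cum0 <- c(0, cumsum(lam_rate * diff(bounds)))
  edges <- seq(0, by = model$bin_width,
               length.out = floor(model$duration / model$bin_width) + 1L)
  idx <- pmin(findInterval(edges, bounds, rightmost.closed = TRUE),
              length(rates))
  idx <- pmax(idx, 1L)
  Lam <- cum0[idx] + lam_rate[idx] * (edges - bounds[idx])
  lambda <- pmax(diff(Lam), 0)
  counts <- stats::rpois(length(lambda), lambda)
  tr <- photon_trace(counts, model$bin_width, id = sprintf("sim-%d", model$seed))
  occ_bright <- if (t_active > 0)
    sum(diff(bounds)[seq_along(rates)] * (rates == model$rate_bright)) / t_active
  else NA_real_
  attr(tr, "meta") <- c(unclass(model),
                        list(t_bleach = t_bleach, occ_bright = occ_bright))
  tr
}

#' Simulate a smooth band spectrum
#'
#' Sum of Gaussian bands sampled on a wavelength grid; used to fabricate
#' emission and extinction spectra for testing the overlap-integral and
#' Forster-radius computations.
#'
#' @param bands Data frame (or list coercible to one) with columns `center`
#'   (nm), `width` (nm, Gaussian sd, positive) and `amplitude`.
#' @param kind `"emission"` or `"extinction"`.
#' @param grid Wavelength grid, nm.  Default 1-nm sampling 400-800 nm.
#' @return A [spectrum].
#' @export
gen_spectra <- function(bands, kind = c("emission", "extinction"),
                        grid = seq(400, 800, by = 1)) {
  kind <- match.arg(kind)
  bands <- as.data.frame(bands)
  if (!all(c("center", "width", "amplitude") %in% names(bands)))
    stop("'bands' needs columns center, width, amplitude")
  if (any(bands$width <= 0)) stop("band widths must be positive")
  v <- rep(0, length(grid))
  for (i in seq_len(nrow(bands)))
    v <- v + bands$amplitude[i] *
      exp(-(grid - bands$center[i])^2 / (2 * bands$width[i]^2))
  spectrum(grid, v, kind)
}
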