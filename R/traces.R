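#' Binned photon-count trace of a single molecule
#'
#' @param counts Non-negative integer photon counts per time bin, in
#'   temporal order.
#' @param bin_width Bin width in seconds, positive.
#' @param id Molecule identifier (metadata).
#' @param quencher_conc Quencher concentration during acquisition, mol/L
#'   (metadata).
#' @return An object of class `photon_trace`.
#' @export
photon_trace <- function(counts, bin_width, id = NA_character_,
                         quencher_conc = NA_real_) {
  if (!length(counts)) stop("empty trace")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("'counts' must be non-negative integers")
  if (!is.numeric(bin_width) || length(bin_width) != 1L ||
      !is.finite(bin_width) || bin_width <= 0)
    stop("'bin_width' must be a single positive number of seconds")
  structure(list(counts = as.integer(round(counts)), bin_width = bin_width,
                 id = id, quencher_conc = quencher_conc),
            class = "photon_trace")
}

#' Accumulate a trace into an intensity histogram
#'
#' Histograms the per-bin photon counts of a trace.  With `nbins = "auto"`
#' the histogram uses one bin per integer count when the maximum count is
#' below 200 (integer-aligned edges at half-integers) and Freedman-Diaconis
#' binning otherwise.  A numeric `nbins` gives that many equal-width bins
#' over the count range, integer-aligned whenever `nbins` covers the range.
#'
#' @param trace A [photon_trace].
#' @param nbins `"auto"` or a positive integer.
#' @return An object of class `intensity_histogram`: list with `mids`
#'   (count-value bin centres), `occupancy` (number of time bins per
#'   histogram bin) and `breaks`.
#' @export
accumulate_histogram <- function(trace, nbins = "auto") {
  stopifnot(inherits(trace, "photon_trace"))
  x <- trace$counts
  rng <- range(x)
  span <- rng[2] - rng[1] + 1L
  integer_bins <- function() seq(rng[1] - 0.5, rng[2] + 0.5, by = 1)
  breaks <- if (identical(nbins, "auto")) {
    if (rng[2] < 200) integer_bins()
    else {
      iqr <- stats::IQR(x)
      h <- if (iqr > 0) 2 * iqr / length(x)^(1/3) else 1
      nb <- max(10L, ceiling(span / h))
      seq(rng[1] - 0.5, rng[2] + 0.5, length.out = nb + 1L)
    }
  } else {
    nb <- as.integer(nbins)
    if (is.na(nb) || nb < 1L) stop("'nbins' must be \"auto\" or a positive integer")
    if (nb >= span) integer_bins()
    else seq(rng[1] - 0.5, rng[2] + 0.5, length.out = nb + 1L)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(list(mids = h$mids, occupancy = h$counts, breaks = h$breaks,
                 n_time_bins = length(x)),
            class = "intensity_histogram")
}

# Weighted quantile of histogram mids by occupancy (deterministic seeds for
# the Gaussian fit).
.wquantile <- function(mids, occ, p) {
  cw <- cumsum(occ) / sum(occ)
  vapply(p, function(pp) mids[which(cw >= pp)[1]], 0)
}

.three_gauss <- function(m, par) {
  mu <- c(par[1], par[1] + par[2], par[1] + par[2] + par[3])
  s <- par[4:6]; a <- par[7:9]
  a[1] * exp(-(m - mu[1])^2 / (2 * s[1]^2)) +
    a[2] * exp(-(m - mu[2])^2 / (2 * s[2]^2)) +
    a[3] * exp(-(m - mu[3])^2 / (2 * s[3]^2))
}

#' Three-Gaussian decomposition of an intensity histogram
#'
#' Least-squares fit of the sum of three Gaussian components to the
#' histogram occupancies, representing the background (post-photobleach),
#' dim (metal-bound) and bright (free probe) states of a blinking trace.
#' The ordering `mean_b < mean_dim < mean_bright` is enforced by
#' construction: the dim and bright means are parameterised as cumulative
#' positive increments above the background mean, which removes
#' label-switching.  Optimisation is Levenberg-Marquardt
#' ([minpack.lm::nls.lm]) from a deterministic set of occupancy-quantile
#' seeds; the start with the lowest residual sum of squares wins.
#'
#' If two components collapse onto each other (separation smaller than the
#' combined widths) the decomposition is still returned but flagged
#' `resolved = FALSE` with a warning: brightness ratios from such fits are
#' not trustworthy.
#'
#' @param hist An `intensity_histogram` with at least 10 occupied bins.
#' @return An object of class `histogram_decomposition`: list with
#'   `components` (data frame: `state` = background/dim/bright, `mean`,
#'   `sigma`, `amplitude`), `rss` and `resolved`.
#' @export
fit_three_gaussians <- function(hist) {
  stopifnot(inherits(hist, "intensity_histogram"))
  m <- hist$mids; occ <- as.numeric(hist$occupancy)
  if (sum(occ > 0) < 10L)
    stop("need at least 10 occupied histogram bins to fit three Gaussians")
  amp_near <- function(mu) {
    vapply(mu, function(x) max(occ[which.min(abs(m - x))], max(occ) / 50), 0)
  }
  seed_sets <- list(c(0.10, 0.50, 0.90), c(0.05, 0.50, 0.95),
                    c(0.20, 0.60, 0.95), c(0.02, 0.30, 0.90))
  span <- diff(range(m))
  lower <- c(min(m) - 1, 0.05, 0.05, rep(0.2, 3), rep(0, 3))
  upper <- c(max(m), span + 1, span + 1, rep(span + 1, 3), rep(2 * max(occ), 3))
  best <- NULL
  for (p in seed_sets) {
    mu0 <- .wquantile(m, occ, p)
    mu0 <- mu0 + cumsum(c(0, diff(mu0) <= 0)) # break ties
    s0 <- pmax(sqrt(pmax(mu0, 1)), 0.5)
    par0 <- c(mu0[1], mu0[2] - mu0[1], mu0[3] - mu0[2], s0, amp_near(mu0))
    par0 <- pmin(pmax(par0, lower), upper)
    res <- tryCatch(
      minpack.lm::nls.lm(par0, lower = lower, upper = upper,
                         fn = function(par) .three_gauss(m, par) - occ,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(res)) {
      rss <- sum(res$fvec^2)
      if (is.null(best) || rss < best$rss) best <- list(par = res$par, rss = rss)
    }
  }
  if (is.null(best)) stop("three-Gaussian fit failed from every start")
  par <- best$par
  mu <- c(par[1], par[1] + par[2], par[1] + par[2] + par[3])
  s <- par[4:6]; a <- par[7:9]
  # a trustworthy three-state decomposition needs each pair of neighbouring
  # components separated by more than the sum of their widths; traces that
  # never bleached (no background population) or bleached before showing
  # both emissive states fail this and get flagged
  resolved <- (mu[2] - mu[1]) > (s[1] + s[2]) &&
              (mu[3] - mu[2]) > (s[2] + s[3]) &&
              all(a > 0)
  if (!resolved)
    warning("histogram decomposition: components not clearly resolved; brightness ratios unreliable")
  structure(list(components = data.frame(state = c("background", "dim", "bright"),
                                         mean = mu, sigma = s, amplitude = a),
                 rss = best$rss, resolved = resolved),
            class = "histogram_decomposition")
}

#' @export
print.histogram_decomposition <- function(x, ...) {
  cat("Three-Gaussian histogram decomposition",
      if (!x$resolved) "(NOT RESOLVED)" else "", "\n")
  print(format(x$components, digits = 4), row.names = FALSE)
  cat(sprintf("  rss = %.4g\n", x$rss))
  invisible(x)
}

#' Dim-state relative quantum yield from a decomposition
#'
#' Background-corrected brightness ratio of the dim to the bright state,
#' `f = (mean_dim - mean_b) / (mean_bright - mean_b)`.  Values outside
#' `[0, 1]` (possible for marginal fits) are flagged via the `"anomaly"`
#' attribute; with `clip = TRUE` they are also clipped into `[0, 1]`, never
#' silently.
#'
#' @param dec A `histogram_decomposition`.
#' @param clip Clip anomalous values into `[0, 1]`.
#' @return The per-trace relative quantum yield (numeric scalar) with
#'   attributes `anomaly` (logical) and, if clipped, `raw`.
#' @export
estimate_fpq <- function(dec, clip = FALSE) {
  stopifnot(inherits(dec, "histogram_decomposition"))
  mu <- dec$components$mean
  if (mu[3] <= mu[1])
    stop("degenerate decomposition: bright mean does not exceed background mean")
  f <- (mu[2] - mu[1]) / (mu[3] - mu[1])
  anomaly <- f < 0 || f > 1
  if (anomaly) {
    warning(sprintf("per-trace f = %.3g outside [0, 1]: flagged as anomaly", f))
    if (clip) {
      raw <- f
      f <- min(max(f, 0), 1)
      attr(f, "raw") <- raw
    }
  }
  attr(f, "anomaly") <- anomaly
  f
}

#' Aggregate per-trace quantum yields over molecules
#'
#' Arithmetic mean and sample standard deviation of per-trace dim-state
#' quantum yields.  Values outside `[0, 1]` by more than `exclusion_margin`
#' are treated as fit failures and excluded from the summary, with a message
#' recording how many were dropped; this keeps broken decompositions from
#' contaminating the per-sample estimate.
#'
#' @param f_values Numeric vector of per-trace estimates (from
#'   [estimate_fpq]).
#' @param exclusion_margin Tolerance beyond `[0, 1]` before a value is
#'   excluded.  Default 0.1.
#' @return An object of class `aggregate_qy`: list with `f_mean`, `f_sd`,
#'   `n_traces`, `n_excluded`.
#' @export
aggregate_traces <- function(f_values, exclusion_margin = 0.1) {
  f_values <- as.numeric(f_values)
  if (!length(f_values)) stop("no per-trace values to aggregate")
  keep <- is.finite(f_values) &
    f_values >= -exclusion_margin & f_values <= 1 + exclusion_margin
  if (any(!keep))
    message(sprintf("aggregate_traces: excluded %d of %d trace value(s) outside [%.2g, %.2g]",
                    sum(!keep), length(f_values), -exclusion_margin,
                    1 + exclusion_margin))
  f <- f_values[keep]
  if (!length(f)) stop("all per-trace values excluded")
  structure(list(f_mean = mean(f),
                 f_sd = if (length(f) > 1L) stats::sd(f) else 0,
                 n_traces = length(f), n_excluded = sum(!keep)),
            class = "aggregate_qy")
}

#' @export
print.aggregate_qy <- function(x, ...) {
  cat(sprintf("Single-molecule dim-state quantum yield: %.3f +/- %.3f (n = %d traces%s)\n",
              x$f_mean, x$f_sd, x$n_traces,
              if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else ""))
  invisible(x)
}

#' Per-trace analysis: histogram, decomposition, quantum yield
#'
#' Convenience wrapper running [accumulate_histogram],
#' [fit_three_gaussians] and [estimate_fpq] on one trace.
#'
#' @param trace A [photon_trace].
#' @param nbins Passed to [accumulate_histogram].
#' @return List with `f`, `decomposition`, `histogram`.
#' @export
analyze_trace <- function(trace, nbins = "auto") {
  h <- accumulate_histogram(trace, nbins)
  dec <- suppressWarnings(fit_three_gaussians(h))
  f <- suppressWarnings(estimate_fpq(dec))
  list(f = as.numeric(f), resolved = dec$resolved, decomposition = dec,
       histogram = h)
}

#' Analyse a set of traces and aggregate
#'
#' Runs [analyze_trace] on every trace and aggregates the per-trace
#' estimates with [aggregate_traces].  By default traces whose decomposition
#' is flagged unresolved (no clear background/dim/bright structure, e.g.
#' molecules that never photobleached during the record or bleached before
#' showing both emissive states) are excluded, the same selection an
#' experimenter applies when picking traces for evaluation; the number
#' dropped is reported.
#'
#' @param traces List of [photon_trace] objects.
#' @param nbins Passed to [accumulate_histogram].
#' @param exclude_unresolved Drop traces with unresolved decompositions
#'   before aggregating.  Default `TRUE`.
#' @return List with `aggregate` (an `aggregate_qy`), `per_trace` (numeric
#'   vector, all traces), and `resolved` (logical vector).
#' @export
analyze_traces <- function(traces, nbins = "auto", exclude_unresolved = TRUE) {
  if (!length(traces)) stop("no traces supplied")
  res <- lapply(traces, analyze_trace, nbins = nbins)
  f <- vapply(res, `[[`, 0, "f")
  ok <- vapply(res, `[[`, TRUE, "resolved")
  use <- if (exclude_unresolved) ok else rep(TRUE, length(f))
  if (any(!use))
    message(sprintf("analyze_traces: %d of %d trace(s) without a resolved three-state decomposition excluded",
                    sum(!use), length(f)))
  if (!any(use)) stop("no trace yielded a resolved three-state decomposition")
  list(aggregate = aggregate_traces(f[use]), per_trace = f, resolved = ok)
}
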