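#' Two-state quenching parameters
#'
#' Bundles the association constant `K` of the probe--metal complex with the
#' residual relative quantum yield `f` of the complexed (dim) species.  The
#' pair parameterises the static-quenching model in which a fluorescent probe
#' `L` reversibly binds a metal ion `M` to form a complex `ML` with reduced,
#' but generally non-zero, emission.
#'
#' @param K Association constant in 1/(mol/L).  Strictly positive.  Exactly
#'   one of `K` and `logK` must be given.
#' @param logK Base-10 logarithm of `K` (the form reported in stability-
#'   constant tables).
#' @param f Residual relative quantum yield of the complex, in `[0, 1]`.
#'   `f = 1` means the complex is as bright as the free probe (no quenching);
#'   `f = 0` (a fully dark complex) is admitted as a limiting input to the
#'   model functions, although fitted values are constrained away from it.
#' @return An object of class `two_state_params`: a list with elements `K`,
#'   `logK` and `f`.
#' @examples
#' p <- two_state_params(logK = 6.95, f = 0.05)
#' approx_ratio(p, c(0, 5, 20) * 1e-6)
#' @export
two_state_params <- function(K = NULL, logK = NULL, f) {
  if (is.null(K) == is.null(logK))
    stop("give exactly one of 'K' and 'logK'")
  if (is.null(K)) K <- 10^logK
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("'K' must be a single positive finite number")
  if (!is.numeric(f) || length(f) != 1L || !is.finite(f) || f < 0 || f > 1)
    stop("'f' must be a single number in [0, 1]")
  structure(list(K = K, logK = log10(K), f = f), class = "two_state_params")
}

#' @export
print.two_state_params <- function(x, ...) {
  cat(sprintf("Two-state quenching parameters: log K = %.4g (K = %.4g M^-1), f = %.4g\n",
              x$logK, x$K, x$f))
  invisible(x)
}

#' Stern-Volmer quenching ratio
#'
#' The linear law `F0/F = 1 + Ksv * c` expected for purely collisional
#' (dynamic) quenching.  Negative curvature of measured data relative to this
#' line is the signature of a different mechanism, here the formation of a
#' partially emissive ground-state complex.
#'
#' @param ksv Stern-Volmer constant in 1/(mol/L), non-negative.
#' @param conc Quencher concentration(s) in mol/L, non-negative.
#' @return The quenching ratio `F0/F`, vectorised over `conc`.
#' @export
stern_volmer_ratio <- function(ksv, conc) {
  if (!is.numeric(ksv) || length(ksv) != 1L || !is.finite(ksv) || ksv < 0)
    stop("'ksv' must be a single non-negative number")
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0))
    stop("'conc' must be non-negative and finite")
  1 + ksv * conc
}

#' Approximate two-state quenching ratio
#'
#' Quenching ratio `F0/F = (1 + K c) / (1 + f K c)` of the two-state model in
#' the approximation that the free quencher concentration equals the total
#' quencher concentration (valid for probe concentrations small compared with
#' `1/K`).  The curve rises with slope `K (1 - f)` at the origin and
#' saturates at `1/f`, producing the negative deviation from the
#' Stern-Volmer line characteristic of static quenching to a dim, not dark,
#' complex.  With `f = 0` it reduces to the static Stern-Volmer form
#' `1 + K c`; with `f = 1` it is identically 1.
#'
#' @param params A [two_state_params] object.
#' @param conc Total quencher concentration(s), mol/L, non-negative.
#' @return `F0/F`, vectorised over `conc`.
#' @seealso [precise_ratio] for the exact mass-balance version.
#' @export
approx_ratio <- function(params, conc) {
  stopifnot(inherits(params, "two_state_params"))
  if (!is.numeric(conc) || any(!is.finite(conc)) || any(conc < 0))
    stop("'conc' must be non-negative and finite")
  Kc <- params$K * conc
  (1 + Kc) / (1 + params$f * Kc)
}

#' Solve the 1:1 binding equilibrium by mass balance
#'
#' Finds the equilibrium complex concentration `ML` for total probe `L0` and
#' total metal `M0` from `K (L0 - ML) (M0 - ML) = ML`.  `ML` is the smaller
#' root of the quadratic `K ML^2 - (K (L0 + M0) + 1) ML + K L0 M0 = 0`,
#' the only root with `0 <= ML <= min(L0, M0)`.  The root is evaluated in
#' the cancellation-free form `2 c / (b + sqrt(b^2 - 4 a c))`, which stays
#' accurate over the full range of stability constants encountered for
#' metal--bipyridine complexes (`K` from about 1e4 to beyond 1e8 1/M).
#'
#' @param K Association constant, 1/(mol/L), positive.
#' @param L0 Total probe concentration, mol/L, non-negative.
#' @param M0 Total metal (quencher) concentration, mol/L, non-negative.
#'   `L0` and `M0` are recycled against each other.
#' @return A data frame of class `equilibrium_state` with columns `L0`, `M0`
#'   and `ML` (all mol/L).
#' @export
solve_equilibrium <- function(K, L0, M0) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0)
    stop("'K' must be a single positive number")
  if (any(!is.finite(L0)) || any(L0 < 0)) stop("'L0' must be non-negative")
  if (any(!is.finite(M0)) || any(M0 < 0)) stop("'M0' must be non-negative")
  n <- max(length(L0), length(M0))
  L0 <- rep_len(L0, n)
  M0 <- rep_len(M0, n)
  b <- K * (L0 + M0) + 1
  cc <- K * L0 * M0
  disc <- b^2 - 4 * K * cc
  # roots are always real; clamp tiny negative round-off
  disc[disc < 0] <- 0
  ML <- 2 * cc / (b + sqrt(disc))
  ML <- pmin(ML, pmin(L0, M0))
  structure(data.frame(L0 = L0, M0 = M0, ML = ML),
            class = c("equilibrium_state", "data.frame"))
}

#' Exact (mass-balance) two-state quenching ratio
#'
#' Quenching ratio of the two-state model with the full 1:1 equilibrium
#' solved by mass balance, so that depletion of both probe and quencher is
#' accounted for.  With bound fraction `x = ML / L0` the ratio is
#' `F0/F = 1 / (1 - (1 - f) x)`.  For `K * L0 << 1` it is indistinguishable
#' from [approx_ratio]; the difference only becomes visible when the bound
#' probe consumes a noticeable fraction of the quencher.
#'
#' @param params A [two_state_params] object.
#' @param L0 Total probe concentration, mol/L, strictly positive.
#' @param M0 Total quencher concentration(s), mol/L, non-negative.
#' @return `F0/F`, vectorised over `M0`.
#' @export
precise_ratio <- function(params, L0, M0) {
  stopifnot(inherits(params, "two_state_params"))
  if (!is.numeric(L0) || length(L0) != 1L || !is.finite(L0) || L0 <= 0)
    stop("'L0' must be a single positive concentration (ratio undefined at L0 = 0)")
  eq <- solve_equilibrium(params$K, L0, M0)
  x <- eq$ML / L0
  1 / (1 - (1 - params$f) * x)
}
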