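#' Wavelength-sampled spectrum
#'
#' @param wavelength Strictly increasing wavelength grid, nm; at least 5
#'   points.
#' @param value Non-negative spectral values: emission in arbitrary units or
#'   molar extinction in 1/(mol/L)/cm.
#' @param kind `"emission"` or `"extinction"`.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelength, value, kind = c("emission", "extinction")) {
  kind <- match.arg(kind)
  if (length(wavelength) != length(value))
    stop("'wavelength' and 'value' must have equal lengths")
  if (length(wavelength) < 5L) stop("a spectrum needs at least 5 points")
  if (any(!is.finite(wavelength)) || is.unsorted(wavelength, strictly = TRUE))
    stop("'wavelength' must be a strictly increasing finite grid")
  if (any(!is.finite(value)) || any(value < 0))
    stop("spectral values must be non-negative and finite")
  structure(list(wavelength = as.numeric(wavelength),
                 value = as.numeric(value), kind = kind),
            class = "spectrum")
}

#' Spectral overlap integral J
#'
#' Overlap integral `J = integral of Fbar_D(lambda) * eps_A(lambda) *
#' lambda^4 dlambda` between the donor emission (area-normalised to 1 on the
#' common wavelength window) and the acceptor molar extinction.  Both
#' spectra are linearly interpolated onto the union of their grids
#' restricted to the overlap window; the integral is evaluated by
#' trapezoidal quadrature.  No extrapolation is performed.  Because the
#' donor spectrum is renormalised on the window, `J` is invariant under
#' rescaling of the raw emission spectrum.
#'
#' @param donor_emission A [spectrum] of kind `"emission"`.
#' @param acceptor_extinction A [spectrum] of kind `"extinction"`.
#' @return `J` in M^-1 cm^-1 nm^4.  Disjoint supports give `J = 0` with a
#'   warning.
#' @export
overlap_integral <- function(donor_emission, acceptor_extinction) {
  stopifnot(inherits(donor_emission, "spectrum"),
            inherits(acceptor_extinction, "spectrum"))
  if (donor_emission$kind != "emission")
    stop("'donor_emission' must be of kind \"emission\"")
  if (acceptor_extinction$kind != "extinction")
    stop("'acceptor_extinction' must be of kind \"extinction\"")
  lo <- max(min(donor_emission$wavelength), min(acceptor_extinction$wavelength))
  hi <- min(max(donor_emission$wavelength), max(acceptor_extinction$wavelength))
  if (lo >= hi) {
    warning("spectra have disjoint wavelength supports: J = 0")
    return(0)
  }
  grid <- sort(unique(c(donor_emission$wavelength, acceptor_extinction$wavelength,
                        lo, hi)))
  grid <- grid[grid >= lo & grid <= hi]
  fd <- stats::approx(donor_emission$wavelength, donor_emission$value,
                      xout = grid)$y
  ea <- stats::approx(acceptor_extinction$wavelength, acceptor_extinction$value,
                      xout = grid)$y
  area <- pracma::trapz(grid, fd)
  if (area <= 0) stop("donor emission integrates to zero on the overlap window")
  pracma::trapz(grid, (fd / area) * ea * grid^4)
}

#' Forster radius from the overlap integral
#'
#' `R0 = 0.02108 * (kappa2 * n^-4 * phi_d * J)^(1/6)` nanometres, with `J`
#' in M^-1 cm^-1 nm^4.  The numeric prefactor is the standard
#' nanometre-units constant (it absorbs the physical constants of the
#' dipole-dipole transfer-rate expression); `R0` grows only with the sixth
#' root of `J`, so order-of-magnitude changes in spectral overlap move the
#' radius modestly.
#'
#' @param J Overlap integral, M^-1 cm^-1 nm^4, non-negative.
#' @param kappa2 Orientation factor, non-negative; 2/3 for freely rotating
#'   dipoles.
#' @param n Refractive index of the medium, positive; 1.33 for aqueous
#'   buffer.
#' @param phi_d Donor fluorescence quantum yield in (0, 1].
#' @return An object of class `forster_result`: list with `J`, `R0` (nm) and
#'   `params`.
#' @export
forster_radius <- function(J, kappa2 = 2/3, n = 1.33, phi_d = 0.1) {
  if (!is.numeric(J) || length(J) != 1L || !is.finite(J) || J < 0)
    stop("'J' must be a single non-negative number")
  if (!is.finite(kappa2) || kappa2 < 0) stop("'kappa2' must be non-negative")
  if (!is.finite(n) || n <= 0) stop("'n' must be positive")
  if (!is.finite(phi_d) || phi_d <= 0 || phi_d > 1)
    stop("'phi_d' must be in (0, 1]")
  R0 <- 0.02108 * (kappa2 * n^-4 * phi_d * J)^(1/6)
  structure(list(J = J, R0 = R0,
                 params = list(kappa2 = kappa2, n = n, phi_d = phi_d)),
            class = "forster_result")
}

#' @export
print.forster_result <- function(x, ...) {
  cat(sprintf("Forster radius R0 = %.3f nm (J = %.4g M^-1 cm^-1 nm^4; kappa2 = %.4g, n = %.3g, phi_d = %.3g)\n",
              x$R0, x$J, x$params$kappa2, x$params$n, x$params$phi_d))
  invisible(x)
}
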