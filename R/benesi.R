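#' Absorbance titration for Benesi-Hildebrand analysis
#'
#' An absorbance titration of the probe against increasing metal
#' concentration, evaluated at a single wavelength on one wing of the
#' isosbestic point (where the two interconverting species differ most in
#' extinction).
#'
#' @param metal_conc Metal concentrations, mol/L, strictly increasing.
#' @param absorbance Absorbance at `lambda_eval` for each metal
#'   concentration.
#' @param L0 Total probe concentration, mol/L, positive.
#' @param d Optical path length, cm, positive.
#' @param A0 Absorbance at zero metal.
#' @param lambda_eval Evaluation wavelength, nm (metadata only).
#' @return An object of class `absorbance_titration`.
#' @export
absorbance_titration <- function(metal_conc, absorbance, L0, d, A0,
                                 lambda_eval = NA_real_) {
  if (length(metal_conc) != length(absorbance))
    stop("'metal_conc' and 'absorbance' must have equal lengths")
  if (any(!is.finite(metal_conc)) || any(metal_conc < 0))
    stop("'metal_conc' must be non-negative")
  if (is.unsorted(metal_conc, strictly = TRUE))
    stop("'metal_conc' must be strictly increasing")
  if (!is.numeric(L0) || length(L0) != 1L || !is.finite(L0) || L0 <= 0)
    stop("'L0' must be a single positive concentration")
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0)
    stop("path length 'd' must be a single positive number")
  if (!is.numeric(A0) || length(A0) != 1L || !is.finite(A0))
    stop("'A0' must be a single finite number")
  structure(list(metal_conc = as.numeric(metal_conc),
                 absorbance = as.numeric(absorbance),
                 L0 = L0, d = d, A0 = A0, lambda_eval = lambda_eval),
            class = "absorbance_titration")
}

#' Benesi-Hildebrand transform of an absorbance titration
#'
#' Maps each titration row to the point
#' `(x, y) = (metal_conc, d * L0 * metal_conc / (A - A0))`.  For 1:1 binding
#' in the excess-metal regime `y` is linear in `x` with slope `1/delta_eps`
#' and intercept `1/(delta_eps * K)`, so `K = slope / intercept`.  Rows with
#' `|A - A0|` below `min_delta_A` are excluded (the transform diverges as
#' `A` approaches `A0`) and reported via a message.
#'
#' @param titr An [absorbance_titration].
#' @param min_delta_A Exclusion floor on `|A - A0|`.  A sensible choice is
#'   3x the absorbance noise level.  Default 0 excludes only exact ties.
#' @return A data frame with columns `x` (mol/L) and `y` (cm mol^2 L^-2, the
#'   conventional BH ordinate), plus attribute `excluded` (row indices).
#' @export
bh_transform <- function(titr, min_delta_A = 0) {
  stopifnot(inherits(titr, "absorbance_titration"))
  dA <- titr$absorbance - titr$A0
  keep <- abs(dA) > max(min_delta_A, 0) & abs(dA) > .Machine$double.eps
  if (any(!keep))
    message(sprintf("bh_transform: excluded %d row(s) with |A - A0| <= %.3g (rows %s)",
                    sum(!keep), max(min_delta_A, .Machine$double.eps),
                    paste(which(!keep), collapse = ", ")))
  if (!any(keep)) stop("all rows excluded: no usable |A - A0|")
  out <- data.frame(x = titr$metal_conc[keep],
                    y = titr$d * titr$L0 * titr$metal_conc[keep] / dA[keep])
  attr(out, "excluded") <- which(!keep)
  out
}

#' Benesi-Hildebrand estimate of the association constant
#'
#' Unweighted ordinary least squares on the [bh_transform]ed points; the
#' association constant is the quotient of the slope and the intercept, with
#' a standard error propagated to `log10 K` from the slope/intercept
#' covariance by the delta method.  A non-positive intercept means a
#' non-physical (negative) constant and is returned as a flagged failure,
#' never as a number.
#'
#' The result also carries a curvature diagnostic: the reduction in residual
#' sum of squares when a quadratic term is added, as a fraction of the total
#' variation of the transformed ordinate.  Titrations
#' generated from the full equilibrium (no excess-metal approximation) bend
#' away from the BH line at low metal concentration, and this statistic
#' makes that deviation visible.
#'
#' @param titr An [absorbance_titration].
#' @param min_delta_A Passed to [bh_transform].
#' @param weights Optional per-point weights for the linear fit (default
#'   unweighted, matching the usual straight-line BH analysis).
#' @return An object of class `bh_fit`: list with `logK`, `se_logK`, `K`,
#'   `slope`, `intercept`, `r2`, `curvature`, `n`, `ok`.
#' @export
bh_fit <- function(titr, min_delta_A = 0, weights = NULL) {
  tp <- bh_transform(titr, min_delta_A)
  if (nrow(tp) < 3L) stop("need at least 3 transformed points for the BH fit")
  fit <- if (is.null(weights)) stats::lm(y ~ x, data = tp)
         else stats::lm(y ~ x, data = tp, weights = weights)
  cf <- stats::coef(fit)
  slope <- cf[["x"]]; intercept <- cf[["(Intercept)"]]
  # noiseless synthetic titrations fit exactly; summary.lm warns about it
  r2 <- suppressWarnings(summary(fit))$r.squared
  fit2 <- stats::lm(y ~ x + I(x^2), data = tp)
  rss1 <- sum(stats::resid(fit)^2); rss2 <- sum(stats::resid(fit2)^2)
  # share of the total variation captured by a quadratic term beyond the
  # line; ~1e-15 or below is round-off, i.e. no real curvature
  tss <- sum((tp$y - mean(tp$y))^2)
  curvature <- if (tss > 0) (rss1 - rss2) / tss else 0
  if (intercept <= 0) {
    warning("BH intercept <= 0: non-physical association constant; fit flagged")
    return(structure(list(logK = NA_real_, se_logK = NA_real_, K = NA_real_,
                          slope = slope, intercept = intercept, r2 = r2,
                          curvature = curvature, n = nrow(tp), ok = FALSE),
                     class = "bh_fit"))
  }
  K <- slope / intercept
  V <- suppressWarnings(stats::vcov(fit))
  grad <- c(-slope / intercept^2, 1 / intercept)    # d(K)/d(intercept, slope)
  se_K <- sqrt(drop(t(grad) %*% V %*% grad))
  se_logK <- se_K / (K * log(10))
  structure(list(logK = log10(K), se_logK = se_logK, K = K, slope = slope,
                 intercept = intercept, r2 = r2, curvature = curvature,
                 n = nrow(tp), ok = TRUE),
            class = "bh_fit")
}

#' @export
print.bh_fit <- function(x, ...) {
  cat("Benesi-Hildebrand fit\n")
  if (!x$ok) {
    cat("  FLAGGED: non-physical intercept", format(x$intercept), "\n")
    return(invisible(x))
  }
  cat(sprintf("  log K = %.4f +/- %.3g (K = %.4g M^-1)\n", x$logK, x$se_logK, x$K))
  cat(sprintf("  r^2 = %.5f, curvature diagnostic = %.3g, n = %d\n",
              x$r2, x$curvature, x$n))
  invisible(x)
}
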