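#' CTRW model parameters
#'
#' Bundle and validate the three continuous-time random-walk (CTRW)
#' parameters: the anomalous diffusion coefficient `D` (mm^2/s, associated
#' with tissue cellularity), the temporal diffusion-heterogeneity exponent
#' `alpha` and the spatial diffusion-heterogeneity exponent `beta` (both
#' dimensionless, in (0, 1]).
#'
#' `D` is stored in mm^2/s throughout the package; the conventional
#' reporting unit 1e-3 mm^2/s is applied only at the reporting boundary
#' (see [report_units()]).
#'
#' @param D anomalous diffusion coefficient, mm^2/s, `D > 0`.
#' @param alpha temporal heterogeneity exponent in (0, 1].
#' @param beta spatial heterogeneity exponent in (0, 1].
#' @return An object of class `ctrw_params` (named list).
#' @examples
#' ctrw_params(D = 1.021e-3, alpha = 0.783, beta = 0.868)
#' @export
ctrw_params <- function(D, alpha, beta) {
  stopifnot(length(D) == 1L, length(alpha) == 1L, length(beta) == 1L)
  if (!is.finite(D) || D <= 0) stop("`D` must be > 0 (mm^2/s)", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(beta) || beta <= 0 || beta > 1) {
    stop("`beta` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(D = D, alpha = alpha, beta = beta), class = "ctrw_params")
}

#' @export
print.ctrw_params <- function(x, ...) {
  cat(sprintf("CTRW parameters: D = %.4g x 1e-3 mm^2/s, alpha = %.4g, beta = %.4g\n",
              x$D * 1e3, x$alpha, x$beta))
  invisible(x)
}

#' Forward CTRW diffusion signal
#'
#' The CTRW signal model \eqn{S = S_0 E_\alpha[-(bD)^\beta]}, where
#' \eqn{E_\alpha} is the Mittag-Leffler function ([ml_eval()]). With
#' `alpha = beta = 1` it reduces exactly to the mono-exponential model.
#'
#' @param params a [ctrw_params()] object.
#' @param S0 signal intensity without diffusion weighting (`S0 > 0`).
#' @param b diffusion weighting, s/mm^2 (vector allowed, `b >= 0`).
#' @return Signal intensities, same length as `b`.
#' @examples
#' p <- ctrw_params(1.021e-3, 0.783, 0.868)
#' ctrw_signal(p, S0 = 1000, b = c(0, 800, 3000))
#' @export
ctrw_signal <- function(params, S0, b) {
  if (!inherits(params, "ctrw_params")) params <- do.call(ctrw_params, as.list(params))
  stopifnot(length(S0) == 1L, is.finite(S0), S0 > 0)
  if (any(!is.finite(b) | b < 0)) stop("`b` must be finite and >= 0", call. = FALSE)
  S0 * ml_eval(params$alpha, -(b * params$D)^params$beta)
}

#' Mono-exponential (ADC) forward signal
#'
#' \eqn{S = S_0 e^{-b \cdot ADC}}, the Gaussian-diffusion signal model.
#'
#' @param adc apparent diffusion coefficient, mm^2/s.
#' @param S0 unweighted signal intensity (`S0 > 0`).
#' @param b diffusion weighting, s/mm^2 (vector allowed, `b >= 0`).
#' @return Signal intensities, same length as `b`.
#' @export
mono_exp_signal <- function(adc, S0, b) {
  stopifnot(length(adc) == 1L, is.finite(adc), length(S0) == 1L, S0 > 0)
  if (any(!is.finite(b) | b < 0)) stop("`b` must be finite and >= 0", call. = FALSE)
  S0 * exp(-b * adc)
}

#' Two-point ADC computation
#'
#' ADC from the unweighted image and a single diffusion-weighted image:
#' \eqn{ADC = \ln(S_0 / S_b) / b}. This is the exact inverse of
#' [mono_exp_signal()] and matches the conventional two-image ADC map
#' (b = 0 and b = 800 s/mm^2 in this package's default acquisition).
#'
#' Non-positive weighted signal gives `NaN` (a flagged invalid voxel, not an
#' error, so that whole maps can be computed in one pass); negative ADC
#' values are possible when `S_b > S0` (noise) and are excluded from ROI
#' statistics downstream rather than clamped here.
#'
#' @param S0 unweighted signal (vector allowed, `> 0`).
#' @param S_b signal at b-value `b` (vector allowed).
#' @param b diffusion weighting, s/mm^2, `b > 0`.
#' @return ADC values in mm^2/s (`NaN` where `S_b <= 0`).
#' @export
adc_two_point <- function(S0, S_b, b) {
  stopifnot(length(b) == 1L, is.finite(b), b > 0)
  if (any(!is.finite(S0) | S0 <= 0)) stop("`S0` must be > 0", call. = FALSE)
  # negative S_b is an expected flagged case, not worth a log() warning
  out <- suppressWarnings(log(S0 / S_b) / b)
  out[!is.finite(out)] <- NaN
  out[S_b <= 0] <- NaN
  out
}

#' Convert diffusion coefficients to reporting units
#'
#' Internal storage is mm^2/s; tables conventionally report
#' `x 1e-3 mm^2/s`. One conversion boundary, applied only when reporting.
#'
#' @param x diffusion coefficient(s) in mm^2/s.
#' @return Value(s) in 1e-3 mm^2/s.
#' @export
report_units <- function(x) x * 1e3
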