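#' Fit configuration for the segmented CTRW fit
#'
#' Controls the two-step voxelwise fit: a mono-exponential estimate of `D`
#' from the low-b images, then a bounded Levenberg-Marquardt fit of
#' `(alpha, beta)` over all b-values with `D` (and the step-1 `S0`) fixed.
#'
#' Defaults: step 1 uses b <= 1000 s/mm^2; `D` is constrained to
#' (1e-6, 1e-2) mm^2/s; `alpha` and `beta` to (0.01, 1] and initialised at
#' 0.9, the centre of the range typically observed in tumour tissue;
#' convergence tolerances 1e-10 with at most 200 iterations. The ADC map is
#' computed from the b = 0 and b = 800 s/mm^2 images only.
#'
#' @param b_max_step1 maximum b-value (s/mm^2) used in the mono-exponential
#'   step.
#' @param adc_b b-value of the weighted image used for the two-point ADC.
#' @param D_bounds lower/upper bounds for `D`, mm^2/s.
#' @param ab_lower lower bound for `alpha` and `beta`.
#' @param ab_init initial values `c(alpha, beta)` for step 2.
#' @param tol relative convergence tolerance passed to the optimizer.
#' @param max_iter maximum optimizer iterations.
#' @return A `fit_config` object (named list).
#' @export
fit_config <- function(b_max_step1 = 1000, adc_b = 800,
                       D_bounds = c(1e-6, 1e-2), ab_lower = 0.01,
                       ab_init = c(0.9, 0.9), tol = 1e-10, max_iter = 200) {
  structure(list(b_max_step1 = b_max_step1, adc_b = adc_b,
                 D_bounds = D_bounds, ab_lower = ab_lower, ab_init = ab_init,
                 tol = tol, max_iter = max_iter,
                 package_version = as.character(utils::packageVersion("ctrwdwi"))),
            class = "fit_config")
}

# fit_status codes shared by all per-voxel results
FIT_OK <- 0L
FIT_CLIPPED <- 1L
FIT_FAILED <- 2L

#' Step 1: mono-exponential D estimate from low-b images
#'
#' Minimises \eqn{\sum_{b \le b_{max}} (S_b - \hat S_0 e^{-b \hat D})^2} in
#' the linear signal domain with a Levenberg-Marquardt solver, initialised
#' from the log-linear regression of \eqn{\ln S} on b. `D` is constrained to
#' `config$D_bounds`; an estimate pinned at a bound is reported with status
#' `clipped` rather than silently accepted.
#'
#' @param signal signal vector over the scheme's b-values.
#' @param scheme a [bvalue_scheme()].
#' @param config a [fit_config()].
#' @return List with `D`, `S0` (mm^2/s and signal units), `status` (one of
#'   `"ok"`, `"clipped"`, `"failed"`), and `rss`.
#' @export
fit_mono_exp_D <- function(signal, scheme, config = fit_config()) {
  stopifnot(inherits(scheme, "bvalue_scheme"), length(signal) == nrow(scheme))
  use <- scheme$b <= config$b_max_step1 & is.finite(signal) & signal > 0
  if (sum(use) < 3L) {
    return(list(D = NA_real_, S0 = NA_real_, status = "failed", rss = NA_real_))
  }
  b <- scheme$b[use]
  s <- signal[use]
  # log-linear initialisation (also the closed-form oracle for exact data)
  co <- stats::coef(stats::lm(log(s) ~ b))
  D0 <- min(max(-co[[2]], config$D_bounds[1]), config$D_bounds[2])
  S00 <- exp(co[[1]])
  fit <- minpack.lm::nls.lm(
    par = c(S0 = S00, D = D0),
    lower = c(1e-12, config$D_bounds[1]),
    upper = c(Inf, config$D_bounds[2]),
    fn = function(p) s - p[1] * exp(-b * p[2]),
    control = minpack.lm::nls.lm.control(
      ftol = config$tol, ptol = config$tol, maxiter = config$max_iter))
  p <- fit$par
  at_bound <- p[["D"]] <= config$D_bounds[1] * (1 + 1e-8) ||
    p[["D"]] >= config$D_bounds[2] * (1 - 1e-8)
  status <- if (fit$info %in% 1:4) {
    if (at_bound) "clipped" else "ok"
  } else if (at_bound) "clipped" else "failed"
  list(D = p[["D"]], S0 = p[["S0"]], status = status, rss = sum(fit$fvec^2))
}

#' Step 2: fit (alpha, beta) with D fixed
#'
#' Minimises \eqn{\sum_b (S_b - S_0 E_\alpha[-(bD)^\beta])^2} over
#' \eqn{(\alpha, \beta) \in (0, 1]^2} with a bound-constrained
#' Levenberg-Marquardt solver, holding `D` and `S0` at their step-1
#' estimates. All b-values (including the high-b shells) participate.
#'
#' @param signal signal vector over the scheme's b-values.
#' @param scheme a [bvalue_scheme()].
#' @param D_fixed the step-1 `D` estimate, mm^2/s.
#' @param S0_fixed the step-1 `S0` estimate.
#' @param config a [fit_config()].
#' @return List with `alpha`, `beta`, `status`, `rss`, `niter`.
#' @export
fit_alpha_beta <- function(signal, scheme, D_fixed, S0_fixed,
                           config = fit_config()) {
  stopifnot(inherits(scheme, "bvalue_scheme"), length(signal) == nrow(scheme))
  if (!is.finite(D_fixed) || D_fixed <= 0 || !is.finite(S0_fixed) || S0_fixed <= 0) {
    return(list(alpha = NA_real_, beta = NA_real_, status = "failed",
                rss = NA_real_, niter = 0L))
  }
  use <- is.finite(signal)
  b <- scheme$b[use]
  s <- signal[use]
  fit <- minpack.lm::nls.lm(
    par = c(alpha = config$ab_init[1], beta = config$ab_init[2]),
    lower = rep(config$ab_lower, 2), upper = c(1, 1),
    fn = function(p) s - S0_fixed * ml_eval(p[1], -(b * D_fixed)^p[2]),
    control = minpack.lm::nls.lm.control(
      ftol = config$tol, ptol = config$tol, maxiter = config$max_iter))
  p <- fit$par
  at_lower <- any(p <= config$ab_lower * (1 + 1e-8))
  status <- if (fit$info %in% 1:4) {
    if (at_lower) "clipped" else "ok"
  } else "failed"
  list(alpha = p[["alpha"]], beta = p[["beta"]], status = status,
       rss = sum(fit$fvec^2), niter = fit$niter)
}

#' Voxelwise segmented CTRW fitting
#'
#' Applies [fit_mono_exp_D()] then [fit_alpha_beta()] to every masked voxel
#' of a [dwi_series()], and computes the two-point ADC map from the b = 0
#' and b = `config$adc_b` volumes. The computation is fully deterministic:
#' fixed initialisation, no randomness.
#'
#' Estimates at the `alpha`/`beta` upper bound 1 are *not* flagged: the CTRW
#' exponents are defined on (0, 1] and the mono-exponential special case
#' legitimately sits at the boundary.
#'
#' @param series a [dwi_series()].
#' @param config a [fit_config()].
#' @return A `parameter_maps` object: 3D arrays `D`, `alpha`, `beta`, `adc`
#'   (mm^2/s where dimensioned), integer `fit_status` (0 ok, 1 clipped,
#'   2 failed, NA outside mask), `rss`, and the `config` used.
#' @export
fit_volume <- function(series, config = fit_config()) {
  stopifnot(inherits(series, "dwi_series"))
  scheme <- series$scheme
  if (!0 %in% scheme$b || !config$adc_b %in% scheme$b) {
    stop(sprintf("scheme must contain b = 0 and b = %g s/mm^2 for the ADC map",
                 config$adc_b), call. = FALSE)
  }
  vol <- dim(series$signal)[1:3]
  nb <- dim(series$signal)[4]
  empty <- array(NA_real_, dim = vol)
  maps <- list(D = empty, alpha = empty, beta = empty, adc = empty,
               fit_status = array(NA_integer_, dim = vol), rss = empty)

  sig_mat <- matrix(series$signal, ncol = nb)  # voxels x b
  vox <- which(series$mask)
  i_b0 <- which(scheme$b == 0)
  i_adc <- which(scheme$b == config$adc_b)
  status_code <- c(ok = FIT_OK, clipped = FIT_CLIPPED, failed = FIT_FAILED)

  for (v in vox) {
    s <- sig_mat[v, ]
    step1 <- fit_mono_exp_D(s, scheme, config)
    if (step1$status == "failed") {
      maps$fit_status[v] <- FIT_FAILED
      next
    }
    step2 <- fit_alpha_beta(s, scheme, step1$D, step1$S0, config)
    maps$D[v] <- step1$D
    maps$alpha[v] <- step2$alpha
    maps$beta[v] <- step2$beta
    maps$rss[v] <- step2$rss
    maps$fit_status[v] <- max(status_code[[step1$status]],
                              status_code[[step2$status]])
  }
  adc <- adc_two_point(pmax(sig_mat[, i_b0], .Machine$double.xmin),
                       sig_mat[, i_adc], config$adc_b)
  adc[sig_mat[, i_b0] <= 0] <- NaN
  adc[!series$mask] <- NA_real_
  maps$adc <- array(adc, dim = vol)

  structure(c(maps, list(config = unclass(config))), class = "parameter_maps")
}

#' @export
print.parameter_maps <- function(x, ...) {
  n_ok <- sum(x$fit_status == FIT_OK, na.rm = TRUE)
  n_all <- sum(!is.na(x$fit_status))
  cat(sprintf("CTRW parameter maps: %d x %d x %d voxels, %d fitted (%d ok)\n",
              dim(x$D)[1], dim(x$D)[2], dim(x$D)[3], n_all, n_ok))
  invisible(x)
}
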