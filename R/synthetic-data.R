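# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so generators are deterministic without
# clobbering the session RNG.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Reference lesion parameter distributions
#'
#' Median and interquartile range of the four diffusion parameters in each
#' pathological group of the bladder-cancer cohort the synthetic generator
#' emulates (ADC and D in 1e-3 mm^2/s; alpha and beta dimensionless).
#'
#' @return A data.frame with columns `group`, `parameter`, `median`, `iqr`.
#' @export
reference_param_distributions <- function() {
  rbind(
    data.frame(group = "low",  parameter = c("adc", "D", "alpha", "beta"),
               median = c(1.421, 1.583, 0.898, 0.870),
               iqr    = c(0.348, 0.682, 0.067, 0.148)),
    data.frame(group = "high", parameter = c("adc", "D", "alpha", "beta"),
               median = c(1.024, 1.021, 0.783, 0.868),
               iqr    = c(0.313, 0.306, 0.099, 0.074)),
    data.frame(group = "pUC",  parameter = c("adc", "D", "alpha", "beta"),
               median = c(1.206, 1.257, 0.860, 0.852),
               iqr    = c(0.418, 0.556, 0.141, 0.114)),
    data.frame(group = "VH",   parameter = c("adc", "D", "alpha", "beta"),
               median = c(0.953, 0.934, 0.774, 0.893),
               iqr    = c(0.225, 0.179, 0.066, 0.064))
  )
}

#' Log-normal calibration from a median and IQR
#'
#' Parameters of a log-normal distribution whose population median equals
#' `med` and whose IQR approximately equals `iqr`:
#' \eqn{\mu = \ln(med)}, \eqn{\sigma = IQR / (med \cdot 2 \Phi^{-1}(0.75))}.
#' The small-\eqn{\sigma} approximation error on the IQR is
#' \eqn{(q\sigma)^2/6} relative (under 0.2% for all calibrated groups).
#'
#' @param med target population median (`> 0`).
#' @param iqr target interquartile range (`> 0`).
#' @return List with `meanlog` and `sdlog` for [stats::rlnorm()].
#' @export
lognormal_calibration <- function(med, iqr) {
  stopifnot(med > 0, iqr > 0)
  list(meanlog = log(med), sdlog = iqr / (med * 2 * stats::qnorm(0.75)))
}

#' Mean of the Rician distribution
#'
#' Closed-form mean of the magnitude of a complex Gaussian signal:
#' \eqn{E|S| = \sigma \sqrt{\pi/2}\, L_{1/2}(-\nu^2 / 2\sigma^2)} with the
#' Laguerre function expressed through modified Bessel functions (evaluated
#' in exponentially scaled form for numerical stability at high SNR). Used
#' as the independent check of the phantom noise generator.
#'
#' @param nu noiseless signal magnitude (vector allowed).
#' @param sigma Gaussian noise scale per channel (`> 0`).
#' @return Expected observed magnitude, same length as `nu`.
#' @export
rician_mean <- function(nu, sigma) {
  stopifnot(sigma > 0)
  x <- nu^2 / (2 * sigma^2)
  i0 <- besselI(x / 2, 0, expon.scaled = TRUE)
  i1 <- besselI(x / 2, 1, expon.scaled = TRUE)
  sigma * sqrt(pi / 2) * ((1 + x) * i0 + x * i1)
}

#' Phantom specification
#'
#' Defines a labelled digital phantom: per-voxel tissue labels, per-label
#' CTRW parameters and S0, the acquisition scheme, the per-excitation SNR at
#' b = 0, and a seed. The default is a 32 x 32 x 1 grid of four equal
#' quadrants whose parameters span the extremes of the reference lesion
#' distributions (low-grade-like, high-grade-like, pUC-like, VH-like
#' tissue).
#'
#' @param dim phantom grid dimensions (length 2 or 3).
#' @param labels integer array of tissue labels (`0` = background); `NULL`
#'   for the default quadrant layout.
#' @param tissue data.frame with columns `label`, `D` (mm^2/s), `alpha`,
#'   `beta`, `S0`; every label present in `labels` must appear.
#' @param scheme a [bvalue_scheme()].
#' @param snr signal-to-noise ratio at b = 0 for a single excitation;
#'   `Inf` for noiseless.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(dim = c(32, 32, 1), labels = NULL,
                         tissue = default_phantom_tissue(),
                         scheme = default_bvalue_scheme(),
                         snr = Inf, seed = 1L) {
  if (length(dim) == 2L) dim <- c(dim, 1L)
  stopifnot(length(dim) == 3L, all(dim >= 1))
  if (is.null(labels)) {
    labels <- array(0L, dim = dim)
    hx <- ceiling(dim[1] / 2); hy <- ceiling(dim[2] / 2)
    labels[1:hx, 1:hy, ] <- 1L
    labels[(hx + 1):dim[1], 1:hy, ] <- 2L
    labels[1:hx, (hy + 1):dim[2], ] <- 3L
    labels[(hx + 1):dim[1], (hy + 1):dim[2], ] <- 4L
  }
  stopifnot(all(dim(labels) == dim))
  present <- setdiff(unique(as.integer(labels)), 0L)
  if (!all(present %in% tissue$label)) {
    stop("every non-zero label must appear in `tissue`", call. = FALSE)
  }
  if (!is.infinite(snr) && (!is.finite(snr) || snr <= 0)) {
    stop("`snr` must be > 0 (Inf for noiseless)", call. = FALSE)
  }
  structure(list(dim = dim, labels = labels, tissue = tissue,
                 scheme = scheme, snr = snr, seed = seed),
            class = "phantom_spec")
}

#' @rdname phantom_spec
#' @export
default_phantom_tissue <- function() {
  data.frame(
    label = 1:4,
    name  = c("low_grade_like", "high_grade_like", "pUC_like", "VH_like"),
    D     = c(1.583e-3, 1.021e-3, 1.257e-3, 0.934e-3),
    alpha = c(0.898, 0.783, 0.860, 0.774),
    beta  = c(0.870, 0.868, 0.852, 0.893),
    S0    = 1000
  )
}

#' Generate a CTRW DWI phantom
#'
#' Simulates the noiseless CTRW signal for every labelled voxel and b-value,
#' then applies Rician noise per excitation -- the observed magnitude is
#' \eqn{\sqrt{(S + g_1)^2 + g_2^2}} with independent Gaussian `g` of scale
#' `S0(b=0)/snr` -- and averages the magnitudes over the scheme's number of
#' excitations for that b-value. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return List with `series` (a [dwi_series()]), `truth` (list of 3D arrays
#'   `D`, `alpha`, `beta`, `adc` of the generating values; `adc` is the
#'   noiseless two-point b0/b800 value implied by the CTRW signal), and
#'   `labels`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, {
    dims <- spec$dim
    nb <- nrow(spec$scheme)
    lab <- as.integer(spec$labels)
    nvox <- prod(dims)
    clean <- matrix(0, nrow = nvox, ncol = nb)
    truth <- list(D = array(NA_real_, dims), alpha = array(NA_real_, dims),
                  beta = array(NA_real_, dims), adc = array(NA_real_, dims))
    has800 <- 800 %in% spec$scheme$b
    for (i in seq_len(nrow(spec$tissue))) {
      row <- spec$tissue[i, ]
      vox <- which(lab == row$label)
      if (!length(vox)) next
      p <- ctrw_params(row$D, row$alpha, row$beta)
      sig <- ctrw_signal(p, row$S0, spec$scheme$b)
      clean[vox, ] <- matrix(sig, nrow = length(vox), ncol = nb, byrow = TRUE)
      truth$D[vox] <- row$D
      truth$alpha[vox] <- row$alpha
      truth$beta[vox] <- row$beta
      if (has800) {
        s800 <- ctrw_signal(p, row$S0, 800)
        truth$adc[vox] <- log(row$S0 / s800) / 800
      }
    }
    observed <- clean
    if (is.finite(spec$snr)) {
      s0_vox <- clean[, which(spec$scheme$b == 0)]
      sigma <- s0_vox / spec$snr
      fg <- lab != 0L
      for (j in seq_len(nb)) {
        nex <- spec$scheme$nex[j]
        acc <- numeric(nvox)
        for (e in seq_len(nex)) {
          g1 <- stats::rnorm(nvox, 0, 1) * sigma
          g2 <- stats::rnorm(nvox, 0, 1) * sigma
          acc <- acc + sqrt((clean[, j] + g1)^2 + g2^2)
        }
        observed[fg, j] <- acc[fg] / nex
      }
    }
    series <- dwi_series(array(observed, dim = c(dims, nb)), spec$scheme,
                         mask = array(lab != 0L, dims))
    list(series = series, truth = truth, labels = spec$labels)
  })
}

#' Generate a synthetic enrollment table
#'
#' One record per screened subject with an exclusion flag. The default
#' counts reproduce a screening flow of 107 subjects of whom 81 remain:
#' 12 without pathologically confirmed urothelial carcinoma, 1 with poor
#' image quality, 4 with lesions under 5 mm, and 9 with incomplete
#' pathological information.
#'
#' @param counts named integer vector of records per exclusion flag;
#'   `"none"` marks enrolled subjects.
#' @param seed integer seed for the output shuffle.
#' @return A data.frame with `subject_id` and `exclusion_flag`.
#' @seealso [filter_enrolled()]
#' @export
generate_enrollment <- function(counts = c(none = 81, no_pathology = 12,
                                           poor_quality = 1, small_lesion = 4,
                                           incomplete_pathology = 9),
                                seed = 1L) {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  flags <- rep(names(counts), times = counts)
  .with_seed(seed, {
    flags <- sample(flags)
    data.frame(
      subject_id = sprintf("S%03d", seq_along(flags)),
      exclusion_flag = factor(flags, levels = names(counts)),
      stringsAsFactors = FALSE
    )
  })
}

#' Filter an enrollment table to the analyzable subjects
#'
#' @param enrollment a data.frame from [generate_enrollment()].
#' @return The rows with `exclusion_flag == "none"`.
#' @export
filter_enrolled <- function(enrollment) {
  stopifnot("exclusion_flag" %in% names(enrollment))
  enrollment[enrollment$exclusion_flag == "none", , drop = FALSE]
}

#' Generate a calibrated synthetic lesion cohort
#'
#' Draws one lesion per row with pathology labels (grade, variant status,
#' T stage) and per-reader mean diffusion parameters. Each lesion's true
#' parameter vector is drawn from log-normal distributions calibrated (via
#' [lognormal_calibration()]) so that the population median and IQR of each
#' parameter in each group of the drawing contrast match the reference
#' distributions; the two reader measurements add independent Gaussian
#' reader noise to the truth and the analyzed value is their average.
#'
#' `group_by` selects which contrast the parameter draws are conditioned on:
#' `"grade"` (default) calibrates the low/high-grade rows exactly and
#' assigns variant labels preferentially to high-grade lesions (variant
#' histology is predominantly a high-grade phenomenon), so the pUC/VH
#' parameter contrast emerges only through its association with grade;
#' `"variant"` calibrates the pUC/VH rows exactly instead, with grade
#' labels assigned preferentially: all low-grade lesions are pure urothelial.
#' Parameters are drawn independently of each other within a lesion.
#'
#' `alpha` and `beta` draws (and reader values) are clipped to (0, 1]; the
#' realised clipping fraction is recorded in the `clip_rate` attribute.
#'
#' @param n_low,n_high lesions per grade group.
#' @param n_pUC,n_VH lesions per variant group (`n_pUC + n_VH` must equal
#'   `n_low + n_high`).
#' @param stage_counts named counts over pathological T stages.
#' @param dist_spec distribution table as [reference_param_distributions()].
#' @param reader_sd_frac per-parameter reader noise standard deviation, as a
#'   fraction of the group median.
#' @param group_by contrast the draws are conditioned on.
#' @param seed integer seed.
#' @return A `cohort_table` data.frame: `lesion_id`, `grade`, `variant`,
#'   `stage`, and for each parameter `p` in adc, D, alpha, beta the columns
#'   `p_true`, `p_r1`, `p_r2`, `p` (reader average). ADC and D are in
#'   1e-3 mm^2/s as conventionally reported.
#' @export
generate_cohort <- function(n_low = 15, n_high = 66, n_pUC = 51, n_VH = 30,
                            stage_counts = c(pTa = 4, pT1 = 39, pT2 = 16,
                                             pT3 = 11, pT4 = 11),
                            dist_spec = reference_param_distributions(),
                            reader_sd_frac = 0.03,
                            group_by = c("grade", "variant"),
                            seed = 1L) {
  group_by <- match.arg(group_by)
  n <- n_low + n_high
  if (n_pUC + n_VH != n) {
    stop("`n_pUC + n_VH` must equal `n_low + n_high`", call. = FALSE)
  }
  if (sum(stage_counts) != n) {
    stop("`stage_counts` must sum to the number of lesions", call. = FALSE)
  }
  params <- c("adc", "D", "alpha", "beta")
  .with_seed(seed, {
    grade <- c(rep("low", n_low), rep("high", n_high))
    # VH is concentrated in the high-grade stratum
    n_vh_high <- min(n_VH, n_high)
    n_vh_low <- n_VH - n_vh_high
    variant <- character(n)
    variant[grade == "high"] <- sample(c(rep("VH", n_vh_high),
                                         rep("pUC", n_high - n_vh_high)))
    variant[grade == "low"] <- sample(c(rep("VH", n_vh_low),
                                        rep("pUC", n_low - n_vh_low)))
    # non-muscle-invasive stages go to low grade first
    stage_pool <- rep(names(stage_counts), times = stage_counts)
    stage <- character(n)
    stage[grade == "low"] <- stage_pool[seq_len(n_low)]
    stage[grade == "high"] <- stage_pool[n_low + seq_len(n_high)]

    draw_group <- if (group_by == "grade") grade else variant
    truth <- matrix(NA_real_, n, length(params),
                    dimnames = list(NULL, params))
    n_clip <- 0L; n_drawn_ab <- 0L
    for (g in unique(draw_group)) {
      rows <- draw_group == g
      for (p in params) {
        cell <- dist_spec[dist_spec$group == g & dist_spec$parameter == p, ]
        if (nrow(cell) != 1L) {
          stop(sprintf("no distribution row for group %s, parameter %s", g, p),
               call. = FALSE)
        }
        cal <- lognormal_calibration(cell$median, cell$iqr)
        x <- stats::rlnorm(sum(rows), cal$meanlog, cal$sdlog)
        if (p %in% c("alpha", "beta")) {
          n_drawn_ab <- n_drawn_ab + length(x)
          n_clip <- n_clip + sum(x > 1)
          x <- pmin(x, 1)
        }
        truth[rows, p] <- x
      }
    }
    out <- data.frame(lesion_id = sprintf("L%03d", seq_len(n)),
                      grade = grade, variant = variant, stage = stage,
                      stringsAsFactors = FALSE)
    for (p in params) {
      med <- vapply(draw_group, function(g) {
        dist_spec$median[dist_spec$group == g & dist_spec$parameter == p]
      }, 0.0)
      sd_r <- reader_sd_frac * med
      r1 <- truth[, p] + stats::rnorm(n, 0, sd_r)
      r2 <- truth[, p] + stats::rnorm(n, 0, sd_r)
      if (p %in% c("alpha", "beta")) {
        r1 <- pmin(pmax(r1, 1e-6), 1)
        r2 <- pmin(pmax(r2, 1e-6), 1)
      } else {
        r1 <- pmax(r1, 1e-6)
        r2 <- pmax(r2, 1e-6)
      }
      out[[paste0(p, "_true")]] <- truth[, p]
      out[[paste0(p, "_r1")]] <- r1
      out[[paste0(p, "_r2")]] <- r2
      out[[p]] <- (r1 + r2) / 2
    }
    ord <- sample.int(n)
    out <- out[ord, ]
    rownames(out) <- NULL
    attr(out, "clip_rate") <- n_clip / n_drawn_ab
    attr(out, "group_by") <- group_by
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
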