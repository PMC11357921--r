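#' Mean parameter value over an ROI
#'
#' Arithmetic mean of a parameter-map channel over the voxels of a region
#' of interest, ignoring `NaN`/`NA` voxels (failed or invalid fits). The
#' number of voxels actually used is reported alongside the mean.
#'
#' @param map 3D numeric array (one channel of a `parameter_maps`).
#' @param mask logical array of the same dimensions; `TRUE` marks ROI
#'   voxels.
#' @return List with `mean` (NA if no usable voxel) and `n_used`.
#' @export
roi_mean <- function(map, mask) {
  stopifnot(is.array(map) || is.numeric(map), length(map) == length(mask))
  vals <- map[which(mask)]
  usable <- vals[is.finite(vals)]
  if (!length(usable)) return(list(mean = NA_real_, n_used = 0L))
  list(mean = mean(usable), n_used = length(usable))
}

#' ROI mask from a phantom tissue label
#'
#' Builds an ROI mask covering one tissue label, optionally eroded by one
#' voxel in-plane to emulate the reader practice of staying clear of lesion
#' margins (necrotic/cystic rim exclusion).
#'
#' @param labels integer label array (as returned by [generate_phantom()]).
#' @param label the tissue label to select.
#' @param erode erode the mask by one voxel in-plane.
#' @return Logical array.
#' @export
label_mask <- function(labels, label, erode = FALSE) {
  m <- labels == label
  if (erode) {
    d <- dim(m)
    for (k in seq_len(d[3])) {
      sl <- m[, , k]
      er <- array(FALSE, d[1:2])
      if (d[1] > 2 && d[2] > 2) {
        i <- 2:(d[1] - 1); j <- 2:(d[2] - 1)
        er[i, j] <- sl[i, j] & sl[i - 1, j] & sl[i + 1, j] &
          sl[i, j - 1] & sl[i, j + 1]
      }
      m[, , k] <- er
    }
  }
  m
}

#' Average the two readers' measurements
#'
#' @param r1,r2 per-lesion values from readers 1 and 2 (vectors allowed).
#' @return Elementwise `(r1 + r2) / 2`; `NA` where either input is
#'   non-finite.
#' @export
average_readers <- function(r1, r2) {
  out <- (r1 + r2) / 2
  out[!is.finite(r1) | !is.finite(r2)] <- NA_real_
  out
}

#' Interobserver agreement: two-way random-effects ICC
#'
#' Single-measure, absolute-agreement intraclass correlation under the
#' two-way random-effects model -- ICC(2,1) in the Shrout-Fleiss taxonomy,
#' ICC(A,1) in McGraw-Wong -- the standard agreement index for two readers
#' measuring the same quantitative imaging biomarker. The 95% confidence
#' interval uses the F-distribution interval with Satterthwaite degrees of
#' freedom. The point estimate is banded as: <= 0.20 poor, 0.21-0.40 fair,
#' 0.41-0.60 moderate, 0.61-0.80 good, 0.81-1.00 perfect.
#'
#' @param reader1,reader2 paired per-lesion measurements (length >= 5).
#' @param conf confidence level for the interval.
#' @return List with `icc`, `ci_low`, `ci_high`, `band`, `n`, and
#'   `degenerate` (TRUE when there is no between-lesion variance to
#'   support an agreement estimate).
#' @export
interobserver_icc <- function(reader1, reader2, conf = 0.95) {
  stopifnot(length(reader1) == length(reader2), length(reader1) >= 5,
            all(is.finite(reader1)), all(is.finite(reader2)))
  x <- cbind(reader1, reader2)
  n <- nrow(x)
  k <- 2L
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  band_of <- function(r) {
    cut(r, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
        labels = c("poor", "fair", "moderate", "good", "perfect"))
  }

  if (msr <= .Machine$double.eps * grand^2) {
    return(list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                band = NA, n = n, degenerate = TRUE))
  }
  if (mse == 0 && msc == 0) {  # identical readers
    return(list(icc = 1, ci_low = 1, ci_high = 1,
                band = band_of(1), n = n, degenerate = FALSE))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  alpha2 <- (1 - conf) / 2
  f_l <- stats::qf(1 - alpha2, n - 1, v)
  f_u <- stats::qf(1 - alpha2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci_low = lower, ci_high = upper,
       band = band_of(icc), n = n, degenerate = FALSE)
}
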