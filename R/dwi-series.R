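#' Multi-b-value acquisition scheme
#'
#' An ordered table of b-values with the per-b number of excitations (NEX).
#' The default scheme is an 11-b-value bladder protocol spanning
#' 0-3000 s/mm^2 with heavier averaging at high b, where the magnitude
#' signal is weakest:
#' b = 0, 50, 100, 200, 400, 800, 1000, 1500, 2000, 2500, 3000 s/mm^2 with
#' NEX = 1, 1, 1, 1, 1, 2, 4, 6, 8, 14, 16.
#'
#' @param b_values strictly increasing b-values, s/mm^2; must start at 0
#'   (the unweighted image is required for S0).
#' @param nex positive integer number of excitations per b-value.
#' @return A `bvalue_scheme` object (data.frame with columns `b`, `nex`).
#' @examples
#' default_bvalue_scheme()
#' bvalue_scheme(c(0, 500, 1000), c(1, 2, 4))
#' @export
bvalue_scheme <- function(b_values, nex = rep(1L, length(b_values))) {
  b_values <- as.numeric(b_values)
  nex <- as.integer(nex)
  if (length(b_values) != length(nex)) {
    stop("`b_values` and `nex` must have the same length", call. = FALSE)
  }
  if (any(diff(b_values) <= 0)) stop("`b_values` must be strictly increasing", call. = FALSE)
  if (b_values[1] != 0) stop("the first b-value must be 0 (S0 image)", call. = FALSE)
  if (any(nex < 1L)) stop("`nex` must be positive integers", call. = FALSE)
  structure(data.frame(b = b_values, nex = nex),
            class = c("bvalue_scheme", "data.frame"))
}

#' @rdname bvalue_scheme
#' @export
default_bvalue_scheme <- function() {
  bvalue_scheme(
    b_values = c(0, 50, 100, 200, 400, 800, 1000, 1500, 2000, 2500, 3000),
    nex      = c(1, 1, 1, 1, 1, 2, 4, 6, 8, 14, 16)
  )
}

#' DWI series container
#'
#' Holds a multi-b-value DWI volume as a 4D array `(x, y, z, b)` together
#' with its acquisition scheme, a foreground mask and voxel spacing. This is
#' the substrate for voxelwise model fitting ([fit_volume()]).
#'
#' If no mask is supplied, one is derived by thresholding the b = 0 volume
#' at 5% of its robust maximum (99th percentile), which excludes air and
#' background the way manual ROI protocols exclude unusable regions.
#'
#' @param signal 4D numeric array, last dimension indexed by b-value (a 3D
#'   array is accepted for single-slice data and promoted to `dim (x,y,1,b)`).
#' @param scheme a [bvalue_scheme()]; its length must match `dim(signal)[4]`.
#' @param mask logical 3D array of foreground voxels, or `NULL` to derive one.
#' @param spacing voxel spacing in mm, length 3.
#' @return A `dwi_series` object (list with `signal`, `scheme`, `mask`,
#'   `spacing`).
#' @export
dwi_series <- function(signal, scheme, mask = NULL, spacing = c(1, 1, 1)) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  if (length(dim(signal)) == 3L) {
    dim(signal) <- c(dim(signal)[1:2], 1L, dim(signal)[3])
  }
  if (length(dim(signal)) != 4L) {
    stop("`signal` must be a 4D (x, y, z, b) array", call. = FALSE)
  }
  if (dim(signal)[4] != nrow(scheme)) {
    stop("4th dimension of `signal` must match the number of b-values", call. = FALSE)
  }
  vol <- dim(signal)[1:3]
  if (is.null(mask)) {
    b0 <- signal[, , , 1, drop = FALSE]
    thr <- 0.05 * stats::quantile(b0, 0.99, names = FALSE)
    mask <- array(b0 >= thr, dim = vol)
  }
  stopifnot(is.logical(mask), all(dim(mask) == vol))
  if (any(signal[rep(mask, times = dim(signal)[4])] < 0, na.rm = TRUE)) {
    stop("`signal` must be non-negative inside the mask", call. = FALSE)
  }
  structure(list(signal = signal, scheme = scheme, mask = mask,
                 spacing = as.numeric(spacing)),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("DWI series: %d x %d x %d voxels, %d b-values (%g-%g s/mm^2), %d masked\n",
              d[1], d[2], d[3], d[4], min(x$scheme$b), max(x$scheme$b), sum(x$mask)))
  invisible(x)
}

#' Read a b-value table
#'
#' Reads a TSV with columns `b_s_mm2` and `nex` into a [bvalue_scheme()].
#'
#' @param path path to the TSV file.
#' @return A [bvalue_scheme()].
#' @export
read_btable <- function(path) {
  tab <- utils::read.delim(path, sep = "\t")
  if (!all(c("b_s_mm2", "nex") %in% names(tab))) {
    stop("b-table must have columns `b_s_mm2` and `nex`", call. = FALSE)
  }
  bvalue_scheme(tab$b_s_mm2, tab$nex)
}

#' Write a b-value table
#'
#' @param scheme a [bvalue_scheme()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_btable <- function(scheme, path) {
  stopifnot(inherits(scheme, "bvalue_scheme"))
  utils::write.table(data.frame(b_s_mm2 = scheme$b, nex = scheme$nex),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 4D DWI NIfTI plus b-table into a DWI series
#'
#' @param dwi_path path to a 4D NIfTI (x, y, z, b).
#' @param btable_path path to the b-table TSV (columns `b_s_mm2`, `nex`).
#' @param mask_path optional path to a 3D NIfTI mask (non-zero = foreground).
#' @return A [dwi_series()].
#' @export
read_dwi_nifti <- function(dwi_path, btable_path, mask_path = NULL) {
  img <- RNifti::readNifti(dwi_path)
  scheme <- read_btable(btable_path)
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- as.array(RNifti::readNifti(mask_path))
    d3 <- c(dim(m), 1L, 1L)[1:3]  # singleton trailing dims may be dropped
    mask <- array(m != 0, dim = d3)
  }
  spacing <- RNifti::pixdim(img)[1:3]
  dwi_series(as.array(img), scheme, mask = mask, spacing = spacing)
}

#' Write parameter maps as NIfTI volumes
#'
#' Writes one 3D NIfTI per map channel (`D`, `alpha`, `beta`, `adc`,
#' `fit_status`, `rss`) plus a JSON sidecar recording the fit
#' configuration.
#'
#' @param maps a `parameter_maps` object from [fit_volume()].
#' @param dir output directory (created if absent).
#' @param spacing voxel spacing in mm for the NIfTI headers.
#' @return The output directory, invisibly.
#' @export
write_parameter_maps <- function(maps, dir, spacing = c(1, 1, 1)) {
  stopifnot(inherits(maps, "parameter_maps"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  channels <- list(D = maps$D, alpha = maps$alpha, beta = maps$beta,
                   adc = maps$adc, fit_status = maps$fit_status, rss = maps$rss)
  for (nm in names(channels)) {
    vol <- channels[[nm]]
    if (nm == "fit_status") vol <- array(as.integer(vol), dim = dim(vol))
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- spacing
    RNifti::writeNifti(img, file.path(dir, paste0(nm, ".nii.gz")))
  }
  jsonlite::write_json(maps$config, file.path(dir, "fit_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
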