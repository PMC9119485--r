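#' 3-D signal volume
#'
#' A plain 3-D intensity array (arbitrary scanner units) with voxel sizes in
#' mm. Array index order is (i, j, k); no world-space resampling is performed.
#'
#' @param signal Numeric 3-D array with finite values.
#' @param voxel_size Length-3 positive numeric, mm per axis.
#' @return An object of class `volume`.
#' @export
volume <- function(signal, voxel_size = c(1, 1, 1)) {
  stopifnot(is.array(signal), length(dim(signal)) == 3)
  if (!all(is.finite(signal))) stop("volume intensities must be finite", call. = FALSE)
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive", call. = FALSE)
  structure(list(signal = signal, voxel_size = as.numeric(voxel_size)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("volume: %s voxels (%.2g x %.2g x %.2g mm), range [%.3g, %.3g]\n",
              paste(dim(x$signal), collapse = " x "),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              min(x$signal), max(x$signal)))
  invisible(x)
}

#' Binary region-of-interest mask
#'
#' A logical 3-D array congruent with a [volume()]. The probabilistic-atlas
#' threshold that produced the mask (e.g. 5% or 25%) is recorded as
#' provenance only; atlas construction itself is upstream of this package.
#'
#' @param mask Logical (or 0/1) 3-D array with at least one voxel set.
#' @param label One of `"locus_coeruleus"`, `"substantia_nigra"`,
#'   `"reference"`, `"custom"`.
#' @param threshold Optional probability threshold provenance (fraction).
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, label = c("custom", "locus_coeruleus",
                                     "substantia_nigra", "reference"),
                     threshold = NA_real_) {
  label <- match.arg(label)
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask must contain at least one voxel", call. = FALSE)
  structure(list(mask = mask, label = label, threshold = threshold),
            class = "roi_mask")
}

check_congruent <- function(vol, roi) {
  stopifnot(inherits(vol, "volume"), inherits(roi, "roi_mask"))
  if (!identical(dim(vol$signal), dim(roi$mask))) {
    stop("mask and volume dimensions differ", call. = FALSE)
  }
}

#' Contrast-to-noise ratio map
#'
#' For every voxel j, `CNR(j) = (x(j) - mu_ref) / sd_ref`, with `mu_ref` and
#' `sd_ref` the mean and standard deviation (n - 1 denominator) of the signal
#' over the reference-region voxels.
#'
#' @param vol A [volume()].
#' @param ref Reference-region [roi_mask()].
#' @return A `volume` of CNR values.
#' @export
compute_cnr_map <- function(vol, ref) {
  check_congruent(vol, ref)
  x <- vol$signal[ref$mask]
  mu <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop("degenerate reference region: zero signal standard deviation", call. = FALSE)
  }
  volume((vol$signal - mu) / s, vol$voxel_size)
}

#' Contrast-ratio map
#'
#' Alternative contrast measure normalized by the reference mean instead of
#' its standard deviation: `CR(j) = (x(j) - mu_ref) / mu_ref`.
#'
#' @inheritParams compute_cnr_map
#' @return A `volume` of CR values.
#' @export
compute_contrast_ratio_map <- function(vol, ref) {
  check_congruent(vol, ref)
  mu <- mean(vol$signal[ref$mask])
  if (mu == 0) stop("degenerate reference region: zero mean signal", call. = FALSE)
  volume((vol$signal - mu) / mu, vol$voxel_size)
}

#' Mean map value over a region of interest
#'
#' @param map A [volume()] (e.g. a CNR map).
#' @param roi An [roi_mask()].
#' @return Arithmetic mean over the ROI voxels.
#' @export
mean_roi_value <- function(map, roi) {
  check_congruent(map, roi)
  mean(map$signal[roi$mask])
}

#' Synthetic neuromelanin-contrast phantom
#'
#' Generates a volume with Gaussian noise around a reference level, a
#' reference-region box, and a small elevated blob whose expected CNR equals
#' `roi_effect` (the elevation is `roi_effect * noise_sd`, so the recovered
#' CNR is invariant to the noise level by construction).
#'
#' @param shape Volume dimensions.
#' @param ref_level Baseline signal level.
#' @param roi_effect Target expected CNR of the blob, in reference-sd units.
#' @param noise_sd Signal noise sd.
#' @param seed Optional integer seed.
#' @return A list with `volume`, `lc` (blob mask) and `reference` mask.
#' @export
generate_phantom <- function(shape = c(24L, 24L, 12L), ref_level = 100,
                             roi_effect = 3, noise_sd = 10, seed = NULL) {
  stopifnot(length(shape) == 3, all(shape >= 8), noise_sd > 0)
  with_seed(seed, {
    sig <- array(stats::rnorm(prod(shape), ref_level, noise_sd), dim = shape)
    ref <- array(FALSE, shape)
    ref[2:(shape[1] %/% 2), 2:(shape[2] - 1), 2:(shape[3] - 1)] <- TRUE
    lc <- array(FALSE, shape)
    lo <- shape[1] %/% 2 + 2L
    lc[lo:min(lo + 2L, shape[1]), (shape[2] %/% 2):(shape[2] %/% 2 + 2L),
       (shape[3] %/% 2):min(shape[3] %/% 2 + 1L, shape[3])] <- TRUE
    if (any(lc & ref)) stop("phantom configuration error: overlapping regions", call. = FALSE)
    sig[lc] <- sig[lc] + roi_effect * noise_sd
    list(volume = volume(sig),
         lc = roi_mask(lc, "locus_coeruleus"),
         reference = roi_mask(ref, "reference"))
  })
}

#' Read a NIfTI volume
#'
#' Thin wrapper over the optional RNifti dependency.
#'
#' @param path NIfTI file path.
#' @return A [volume()].
#' @export
read_volume_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("reading NIfTI requires the RNifti package", call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  volume(array(as.numeric(img), dim = dim(img)),
         voxel_size = RNifti::pixdim(img)[seq_len(3)])
}

#' Write a volume to NIfTI
#'
#' @param vol A [volume()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_volume_nifti <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI requires the RNifti package", call. = FALSE)
  }
  img <- RNifti::asNifti(vol$signal)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
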