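# MRI quantification: ADC parametric mapping from DWI and anatomic tumor
# volumetry / whole-tumor ADC summarization.

#' Compute an ADC parametric map from a diffusion-weighted stack
#'
#' For two b-values the mono-exponential solution is used directly,
#' ADC = ln(S_b0 / S_b1) / (b1 - b0); for more than two the least-squares
#' slope of -ln(S_b) versus b is fitted per voxel. Voxels with any
#' nonpositive signal cannot be log-transformed and are flagged invalid
#' (stored as `NA` and excluded from all downstream statistics) rather
#' than clipped, since clipping would bias the estimate.
#'
#' @param dwi list of elements `list(b = <s/mm2>, vol = <image_volume>)`;
#'   at least two distinct b-values including b = 0, congruent grids.
#' @return an `image_volume` with units `"mm2_per_s"` and attributes
#'   `b_values` and `fit_method` (`"two_point"` or `"least_squares"`).
#' @export
compute_adc_map <- function(dwi) {
  if (length(dwi) < 2L) stop("need >= 2 b-values")
  b <- vapply(dwi, function(e) as.numeric(e$b), numeric(1))
  if (anyDuplicated(b)) stop("b-values must be distinct")
  if (min(b) != 0) stop("a b = 0 acquisition is required")
  vols <- lapply(dwi, `[[`, "vol")
  ref <- vols[[1]]
  for (v in vols) {
    stopifnot(inherits(v, "image_volume"))
    if (!identical(dim(v$values), dim(ref$values)))
      stop("DWI grids are not congruent")
  }
  ord <- order(b)
  b <- b[ord]; vols <- vols[ord]
  nvox <- length(ref$values)
  S <- vapply(vols, function(v) as.numeric(v$values), numeric(nvox))
  valid <- rowSums(S <= 0) == 0
  adc <- rep(NA_real_, nvox)
  if (length(b) == 2L) {
    method <- "two_point"
    adc[valid] <- log(S[valid, 1] / S[valid, 2]) / (b[2] - b[1])
  } else {
    method <- "least_squares"
    # per-voxel OLS slope of -log(S) on b, closed form
    bc <- b - mean(b)
    denom <- sum(bc^2)
    L <- -log(S[valid, , drop = FALSE])
    adc[valid] <- as.numeric(L %*% bc) / denom
  }
  if (!any(valid)) stop("no voxel has positive signal at every b-value")
  out <- image_volume(array(adc, dim = dim(ref$values)),
                      spacing = ref$spacing, origin = ref$origin,
                      units = "mm2_per_s")
  attr(out, "b_values") <- b
  attr(out, "fit_method") <- method
  out
}

#' Anatomic tumor volume from a segmentation mask
#'
#' The summed volume of all segmented voxels: voxel count times voxel
#' volume, the same bookkeeping as summing per-slice segmented areas
#' times slice thickness.
#'
#' @param mask a `voi_mask`.
#' @param spacing optional spacing override (mm), defaults to the mask's.
#' @return volume in mm^3 (0 with a warning for an empty mask).
#' @export
tumor_volume <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "voi_mask"))
  if (is.null(spacing)) spacing <- mask$spacing
  if (mask$empty) {
    warning("empty mask: tumor volume is 0")
    return(0)
  }
  sum(mask$values) * prod(as.numeric(spacing))
}

#' Whole-tumor mean ADC
#'
#' Arithmetic mean of the valid (non-NA) ADC values inside the mask.
#'
#' @param adc an ADC `image_volume` (units `"mm2_per_s"`).
#' @param mask non-empty `voi_mask` on the same grid.
#' @return mean ADC in mm^2/s.
#' @export
adc_mean <- function(adc, mask) {
  stopifnot(inherits(adc, "image_volume"), inherits(mask, "voi_mask"))
  if (!identical(adc$units, "mm2_per_s"))
    stop("adc_mean expects an image in mm2_per_s, got '", adc$units, "'")
  if (!identical(dim(mask$values), dim(adc$values)))
    stop("mask grid does not match ADC grid")
  v <- adc$values[mask$values]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no valid ADC voxels inside the mask")
  mean(v)
}
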