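# Static PET quantification: SUV scaling, tumor segmentation rules
# (40%-of-SUVmax isocontour, fixed SUV threshold), SUVmean/max, MTV, TLG,
# and the liver reference QC metric.

F18_HALF_LIFE_MIN <- 109.77

#' Decay-correct an assayed dose to injection time
#'
#' @param dose_MBq activity at assay time (MBq).
#' @param dt_min minutes from assay to injection (negative if assayed
#'   after injection).
#' @param half_life_min isotope half-life in minutes (default F-18,
#'   109.77 min).
#' @return dose at injection time (MBq): `dose * 2^(-dt / half_life)`.
#' @export
decay_correct_dose <- function(dose_MBq, dt_min,
                               half_life_min = F18_HALF_LIFE_MIN) {
  if (half_life_min <= 0) stop("half-life must be > 0")
  dose_MBq * 2^(-dt_min / half_life_min)
}

#' Convert an activity-concentration volume to SUV
#'
#' SUV = concentration (Bq/ml) x body weight (g) / injected dose (Bq),
#' with tissue density taken as 1 g/ml. The input must be tagged
#' `Bq_per_ml` or `kBq_per_ml` and already decay-corrected to injection
#' time.
#'
#' @param activity an `image_volume` in Bq/ml or kBq/ml.
#' @param meta a [scan_meta()] with dose and weight.
#' @return an `image_volume` with units `"SUV"`.
#' @export
to_suv <- function(activity, meta) {
  stopifnot(inherits(activity, "image_volume"), inherits(meta, "scan_meta"))
  scale <- switch(activity$units,
                  Bq_per_ml = 1,
                  kBq_per_ml = 1000,
                  stop("to_suv requires Bq_per_ml or kBq_per_ml input, got '",
                       activity$units, "'"))
  f <- scale * meta$body_weight_g / (meta$injected_dose_MBq * 1e6)
  image_volume(activity$values * f, spacing = activity$spacing,
               origin = activity$origin, units = "SUV")
}

# --- 26-connected component extraction ------------------------------------

# flood fill over `thr` (logical 3D array) from linear seed index, using
# 26-neighbourhood connectivity; returns logical array of the component.
flood26 <- function(thr, seed) {
  d <- dim(thr)
  dp <- d + 2L
  pad <- array(FALSE, dp)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- thr
  # linear-index offsets of the 26 neighbours in the padded array
  nb <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  nb <- nb[!(nb$di == 0 & nb$dj == 0 & nb$dk == 0), ]
  offs <- nb$di + nb$dj * dp[1] + nb$dk * dp[1] * dp[2]
  sij <- arrayInd(seed, d)
  pseed <- (sij[1] + 1L) + sij[2] * dp[1] + sij[3] * dp[1] * dp[2]
  if (!pad[pseed]) stop("seed voxel is below threshold")
  comp <- array(FALSE, dp)
  frontier <- pseed
  comp[frontier] <- TRUE
  while (length(frontier)) {
    cand <- unique(as.vector(outer(frontier, offs, `+`)))
    cand <- cand[pad[cand] & !comp[cand]]
    comp[cand] <- TRUE
    frontier <- cand
  }
  comp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), drop = FALSE]
}

effective_region <- function(suv, search, exclusions) {
  stopifnot(inherits(suv, "image_volume"), inherits(search, "voi_mask"))
  if (!identical(dim(search$values), dim(suv$values)))
    stop("search mask grid does not match image grid")
  eff <- search$values
  for (ex in exclusions) {
    stopifnot(inherits(ex, "voi_mask"))
    if (!identical(dim(ex$values), dim(suv$values)))
      stop("exclusion mask grid does not match image grid")
    eff <- eff & !ex$values
  }
  eff
}

#' Isocontour tumor segmentation at a fraction of SUVmax
#'
#' Finds SUVmax within the search region (minus exclusions), thresholds at
#' `fraction * SUVmax`, and keeps the 26-connected component containing
#' the maximum voxel. Using the connected component reproduces an
#' isocontour tool grown from the lesion hot spot rather than a global
#' threshold that would also pick up kidneys and bladder. Voxels with
#' SUV >= threshold are included, so the maximum voxel always survives
#' (including degenerate uniform images).
#'
#' @param suv an `image_volume` in SUV units.
#' @param search `voi_mask` search region.
#' @param exclusions list of `voi_mask` to remove (e.g. bladder, kidneys).
#' @param fraction isocontour fraction of SUVmax (default 0.40).
#' @return list with `mask` (`voi_mask`), `threshold` (full precision),
#'   `threshold_display` (rounded to 1 decimal, the conventional way such
#'   thresholds are reported), and `suv_max`.
#' @export
segment_iso40 <- function(suv, search, exclusions = list(), fraction = 0.40) {
  eff <- effective_region(suv, search, exclusions)
  if (!any(eff)) stop("effective search region is empty")
  vals <- suv$values
  idx_eff <- which(eff)
  suv_max <- max(vals[idx_eff])
  threshold <- fraction * suv_max
  thr <- eff & (vals >= threshold)
  seed <- idx_eff[which.max(vals[idx_eff])]
  comp <- flood26(thr, seed)
  mask <- voi_mask(comp, label = "tumor_iso40", spacing = suv$spacing,
                   origin = suv$origin)
  list(mask = mask, threshold = threshold,
       threshold_display = round(threshold, 1), suv_max = suv_max)
}

#' Fixed-threshold tumor segmentation
#'
#' Keeps all voxels with SUV >= `threshold` in the search region minus
#' exclusions -- no connectivity filter, matching a plain fixed-SUV rule
#' in which every qualifying voxel is tumor. An empty result is allowed
#' and flagged rather than raised as an error.
#'
#' @inheritParams segment_iso40
#' @param threshold absolute SUV cutoff (default 2.5).
#' @return a `voi_mask` (check `$empty`), with attribute `threshold`.
#' @export
segment_fixed <- function(suv, search, exclusions = list(), threshold = 2.5) {
  eff <- effective_region(suv, search, exclusions)
  mask <- voi_mask(eff & (suv$values >= threshold), label = "tumor_fixed",
                   spacing = suv$spacing, origin = suv$origin)
  attr(mask, "threshold") <- threshold
  mask
}

#' Static metabolic metrics over a tumor VOI
#'
#' @param suv an `image_volume` in SUV units.
#' @param mask non-empty `voi_mask` on the same grid.
#' @param rule optional tag (`"iso40"` or `"fixed"`), carried through.
#' @return object of class `static_metrics`: `suv_max`, `suv_mean`,
#'   `mtv_mm3` (voxel count x voxel volume), `tlg` (= suv_mean x mtv),
#'   `n_voxels`, `rule`.
#' @export
static_metrics <- function(suv, mask, rule = NA_character_) {
  stopifnot(inherits(suv, "image_volume"), inherits(mask, "voi_mask"))
  if (!identical(dim(mask$values), dim(suv$values)))
    stop("mask grid does not match image grid")
  if (mask$empty) stop("static metrics of an empty mask are undefined")
  v <- suv$values[mask$values]
  mtv <- length(v) * voxel_volume(suv)
  smean <- mean(v)
  structure(list(suv_max = max(v), suv_mean = smean, mtv_mm3 = mtv,
                 tlg = smean * mtv, n_voxels = length(v), rule = rule),
            class = "static_metrics")
}

#' @export
print.static_metrics <- function(x, ...) {
  cat(sprintf(
    "<static_metrics%s> SUVmax %.2f, SUVmean %.2f, MTV %.1f mm3, TLG %.1f (%d voxels)\n",
    if (is.na(x$rule)) "" else paste0(" ", x$rule), x$suv_max, x$suv_mean,
    x$mtv_mm3, x$tlg, x$n_voxels))
  invisible(x)
}

#' Mean liver SUV (per-scan quality-control reference)
#'
#' Murine liver background is far below the 2.0-3.0 SUV typical of human
#' livers, which is why a fixed 2.5-SUV tumor threshold under-segments
#' mouse tumors; the liver mean is reported per scan as a QC reference.
#'
#' @param suv an `image_volume` in SUV units.
#' @param liver_mask non-empty `voi_mask`.
#' @return mean SUV over the liver mask.
#' @export
liver_reference <- function(suv, liver_mask) {
  stopifnot(inherits(suv, "image_volume"), inherits(liver_mask, "voi_mask"))
  if (!identical(dim(liver_mask$values), dim(suv$values)))
    stop("liver mask grid does not match image grid")
  if (liver_mask$empty) stop("liver mask is empty")
  mean(suv$values[liver_mask$values])
}
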