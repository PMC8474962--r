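# Dynamic PET quantification: TAC extraction, image-derived input function,
# Patlak graphical analysis, metabolic rate of FDG.

#' Kinetic analysis configuration
#'
#' @param lumped_constant FDG/glucose lumped constant (default 0.6).
#' @param blood_glucose_mmol_l blood glucose (default 6.0 mmol/l,
#'   equivalently 6.0 umol/ml).
#' @param t_star_min Patlak linear-phase start time (default 20 min).
#' @param idif_voxels number of hottest voxels averaged for the
#'   image-derived input function (default 7).
#' @return object of class `kinetic_config`.
#' @export
kinetic_config <- function(lumped_constant = 0.6, blood_glucose_mmol_l = 6.0,
                           t_star_min = 20, idif_voxels = 7L) {
  vals <- c(lumped_constant, blood_glucose_mmol_l, t_star_min, idif_voxels)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all kinetic_config values must be strictly positive")
  structure(list(lumped_constant = lumped_constant,
                 blood_glucose_mmol_l = blood_glucose_mmol_l,
                 t_star_min = t_star_min,
                 idif_voxels = as.integer(idif_voxels)),
            class = "kinetic_config")
}

#' Extract a regional time-activity curve from a dynamic series
#'
#' @param series a `dynamic_series`.
#' @param mask a non-empty `voi_mask` congruent to the series grid.
#' @return a [tac()] of per-frame in-mask mean concentrations versus frame
#'   mid-times in minutes.
#' @export
extract_tac <- function(series, mask) {
  stopifnot(inherits(series, "dynamic_series"), inherits(mask, "voi_mask"))
  if (!identical(dim(mask$values), dim(series$frames[[1]]$values)))
    stop("mask grid does not match series grid")
  if (mask$empty) stop("cannot extract a TAC from an empty mask")
  sel <- which(mask$values)
  conc <- vapply(series$frames, function(f) mean(f$values[sel]), numeric(1))
  tac(mid_times(series$schedule, "min"), conc,
      units = series$frames[[1]]$units)
}

#' Image-derived input function from the hottest vena-cava voxels
#'
#' Within a search box over the vena cava, voxels are ranked by their
#' summed concentration over the bolus window (frames with mid-time <=
#' `rank_window_s`); the top `k` voxels (ties broken by ascending voxel
#' index) form a fixed set whose per-frame mean is the IDIF. A QC flag
#' records whether the curve has the expected single early peak (maximum
#' before 5 min followed by decay), mirroring visual inspection of bolus
#' shape.
#'
#' @param series a `dynamic_series` in concentration units.
#' @param cava_box `voi_mask` containing at least `k` voxels.
#' @param k number of hottest voxels (default 7).
#' @param rank_window_s ranking window in seconds (default 60).
#' @return a [tac()] with attributes `voxels` (linear indices of the
#'   selected set) and `qc_peak_ok` (logical).
#' @export
derive_idif <- function(series, cava_box, k = 7L, rank_window_s = 60) {
  stopifnot(inherits(series, "dynamic_series"), inherits(cava_box, "voi_mask"))
  if (!identical(dim(cava_box$values), dim(series$frames[[1]]$values)))
    stop("cava box grid does not match series grid")
  sel <- which(cava_box$values)
  if (length(sel) < k)
    stop("cava box has ", length(sel), " voxels; k = ", k, " requested")
  mid_s <- mid_times(series$schedule, "s")
  early <- which(mid_s <= rank_window_s)
  if (!length(early)) early <- 1L
  score <- rowSums(vapply(early, function(i) series$frames[[i]]$values[sel],
                          numeric(length(sel))))
  ord <- order(-score, sel)          # hottest first, ties by voxel index
  hot <- sel[ord[seq_len(k)]]
  conc <- vapply(series$frames, function(f) mean(f$values[hot]), numeric(1))
  out <- tac(mid_times(series$schedule, "min"), conc,
             units = series$frames[[1]]$units)
  pk <- which.max(conc)
  qc <- out$mid_min[pk] < 5 &&
    (pk == length(conc) || all(conc[pk] >= conc[seq(min(pk + 1, length(conc)),
                                                    length(conc))] - 1e-12))
  attr(out, "voxels") <- hot
  attr(out, "qc_peak_ok") <- qc
  out
}

#' Patlak graphical analysis of an irreversible tracer
#'
#' Computes the Patlak coordinates
#' \eqn{x_i = \int_0^{t_i} C_p \, d\tau \; / \; C_p(t_i)},
#' \eqn{y_i = C_T(t_i) / C_p(t_i)} (trapezoidal integration anchored at
#' (0, 0)) and fits ordinary least squares to the frames with mid-time
#' >= `t_star_min`. The slope is the net influx constant Ki, the intercept
#' the effective distribution volume. Fits whose relative standard error
#' of Ki is >= 10% fail the quality gate and are flagged.
#'
#' @param ct tumor [tac()] (kBq/ml or SUV).
#' @param cp input-function [tac()] on the same time grid.
#' @param t_star_min start of the linear phase (min), default 20.
#' @return object of class `patlak_result`: fields `ki`, `intercept`,
#'   `se_ki`, `rel_se_pct`, `r2`, `n_points`, `t_star_min`, `qc_pass`,
#'   plus the fitted coordinates `x`, `y`.
#' @export
patlak_fit <- function(ct, cp, t_star_min = 20) {
  stopifnot(inherits(ct, "tac"), inherits(cp, "tac"))
  if (length(ct) != length(cp) ||
      max(abs(ct$mid_min - cp$mid_min)) > 1e-9)
    stop("tumor and input TACs must share one time grid")
  t <- ct$mid_min
  use <- which(t >= t_star_min - 1e-9)
  if (length(use) < 3L)
    stop("need >= 3 frames with mid-time >= t* (have ", length(use), ")")
  if (any(cp$conc[use] <= 0))
    stop("nonpositive input concentration at used frame(s) ",
         paste(use[cp$conc[use] <= 0], collapse = ", "))
  auc <- cumtrapz(c(0, t), c(0, cp$conc))[-1]    # anchored at (0, 0)
  x <- auc[use] / cp$conc[use]
  y <- ct$conc[use] / cp$conc[use]
  n <- length(use)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  if (sxx <= 0) stop("degenerate Patlak abscissa (no spread)")
  ki <- sum((x - xbar) * (y - ybar)) / sxx
  v0 <- ybar - ki * xbar
  resid <- y - (ki * x + v0)
  sse <- sum(resid^2)
  sst <- sum((y - ybar)^2)
  se_ki <- sqrt(sse / (n - 2) / sxx)
  rel_se <- if (ki != 0) 100 * se_ki / abs(ki) else Inf
  r2 <- if (sst > 0) 1 - sse / sst else 1
  structure(list(ki = ki, intercept = v0, se_ki = se_ki,
                 rel_se_pct = rel_se, r2 = r2, n_points = n,
                 t_star_min = t_star_min, qc_pass = rel_se < 10,
                 x = x, y = y),
            class = "patlak_result")
}

#' @export
print.patlak_result <- function(x, ...) {
  cat(sprintf(
    "<patlak_result> Ki = %.5f ml/min/ml (SE %.2f%%%s), V = %.3f, r2 = %.4f, n = %d, t* = %g min\n",
    x$ki, x$rel_se_pct, if (x$qc_pass) "" else ", FAILS <10% gate",
    x$intercept, x$r2, x$n_points, x$t_star_min))
  invisible(x)
}

#' Metabolic rate of FDG from the net influx constant
#'
#' MRglc-type conversion: `MR_FDG = Ki * blood_glucose / lumped_constant`.
#' With the defaults (glucose 6.0 umol/ml, lumped constant 0.6) the factor
#' is 10, so Ki = 0.039 gives 0.39 umol min^-1 ml^-1.
#'
#' @param ki net influx constant (ml min^-1 ml^-1).
#' @param cfg a [kinetic_config()].
#' @return metabolic rate of FDG in umol min^-1 ml^-1.
#' @export
mrfdg <- function(ki, cfg = kinetic_config()) {
  stopifnot(inherits(cfg, "kinetic_config"))
  ki * cfg$blood_glucose_mmol_l / cfg$lumped_constant
}
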