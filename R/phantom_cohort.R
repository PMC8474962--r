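# Cohort-level generators: a TAC-level dynamic PET cohort with count
# noise, and the longitudinal imaging cohort table (weekly tumor growth,
# PET coupling, treatment effects) with known per-scan truth.

#' Frame-averaged input-function TAC
#'
#' Averages the bolus input over each frame interval on a fine grid --
#' what an ideal blood-pool ROI would measure.
#'
#' @param aif [aif_params()].
#' @param schedule a [frame_schedule()].
#' @param dt_s fine-grid step (s).
#' @return a [tac()].
#' @export
aif_frame_tac <- function(aif, schedule = dynamic_1h_schedule(), dt_s = 0.1) {
  end_s <- max(schedule$starts_s + schedule$durations_s)
  t_min <- seq(0, by = dt_s / 60, length.out = ceiling(end_s / dt_s) + 1L)
  cp <- feng_aif(aif, t_min)
  tac(mid_times(schedule, "min"), frame_average(cp, t_min * 60, schedule))
}

#' Add count-based Poisson noise to a regional TAC
#'
#' Expected counts per frame are `N = C * roi_volume * duration *
#' sensitivity` (C in Bq/ml); a Poisson sample is back-converted to
#' concentration. This reproduces the duration dependence that makes the
#' early 2-s frames noisy and the late 600-s frames quiet.
#'
#' @param clean a [tac()] in kBq/ml.
#' @param roi_ml region volume in ml.
#' @param schedule matching [frame_schedule()].
#' @param sensitivity counts per (Bq s).
#' @return a noisy [tac()].
#' @export
add_tac_count_noise <- function(clean, roi_ml, schedule, sensitivity = 0.08) {
  stopifnot(inherits(clean, "tac"), inherits(schedule, "frame_schedule"))
  if (length(clean) != length(schedule)) stop("TAC/schedule length mismatch")
  f <- 1000 * roi_ml * schedule$durations_s * sensitivity
  tac(clean$mid_min, safe_rpois(pmax(clean$conc, 0) * f) / f,
      units = clean$units)
}

# draw from a lognormal with given arithmetic mean and CV, truncated
rlnorm_mean <- function(n, mean, cv, lower = -Inf, upper = Inf) {
  sdlog <- sqrt(log(1 + cv^2))
  if (sdlog == 0) return(rep(mean, n))
  meanlog <- log(mean) - sdlog^2 / 2
  x <- rlnorm(n, meanlog, sdlog)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- rlnorm(sum(bad), meanlog, sdlog)
    bad <- x < lower | x > upper
  }
  x
}

#' Simulate a dynamic PET scan cohort at the TAC level
#'
#' Draws per-scan tumor kinetics around the cohort-typical values
#' (Ki centered on 0.039 ml/min/ml within [0.015, 0.055], i.e. MR_FDG
#' centered on 0.39 within the observed cohort range at the default
#' glucose/lumped-constant conversion), per-scan bolus amplitude, and a
#' per-scan tumor ROI volume; simulates the noiseless frame-averaged
#' tumor TAC and input function and applies count noise (tumor ROI at its
#' drawn volume, input ROI at `idif_voxels` voxels of `voxel_mm` size).
#'
#' @param n_scans number of dynamic scans (default 24).
#' @param seed RNG seed.
#' @param schedule a [frame_schedule()].
#' @param aif base [aif_params()].
#' @param sensitivity counts per (Bq s); 0 disables noise.
#' @param idif_voxels input ROI size in voxels (default 7).
#' @param voxel_mm isotropic voxel size (default 0.4 mm).
#' @param ki_mean,ki_cv,ki_range Ki sampling (ml/min/ml).
#' @return list of scans; each has `tumor` and `idif` ([tac()]s with
#'   noise), `tumor_clean`, `idif_clean`, `ki_true`, `kin`, `tumor_ml`.
#' @export
simulate_tac_cohort <- function(n_scans = 24, seed = 42L,
                                schedule = dynamic_1h_schedule(),
                                aif = aif_params(), sensitivity = 0.08,
                                idif_voxels = 7L, voxel_mm = 0.4,
                                ki_mean = 0.039, ki_cv = 0.22,
                                ki_range = c(0.015, 0.055)) {
  cava_ml <- idif_voxels * voxel_mm^3 * 1e-3
  with_seed(seed, {
    lapply(seq_len(n_scans), function(s) {
      amp <- rlnorm_mean(1, 1, 0.12)
      ai <- aif_params(A1 = aif$A1 * amp, A2 = aif$A2 * amp,
                       A3 = aif$A3 * amp, lam1 = aif$lam1,
                       lam2 = aif$lam2, lam3 = aif$lam3)
      ki <- rlnorm_mean(1, ki_mean, ki_cv, ki_range[1], ki_range[2])
      K1 <- max(rlnorm_mean(1, 0.24, 0.2), ki / 0.45)
      k2 <- rlnorm_mean(1, 0.36, 0.2)
      k3 <- ki * k2 / (K1 - ki)
      kin <- two_tc_params(K1 = K1, k2 = k2, k3 = k3,
                           vb = runif(1, 0.03, 0.08))
      tumor_ml <- rlnorm_mean(1, 0.35, 0.5, 0.06, 1.2)
      tumor_clean <- simulate_2tc_tac(ai, kin, schedule)
      idif_clean <- aif_frame_tac(ai, schedule)
      if (sensitivity > 0) {
        tumor <- add_tac_count_noise(tumor_clean, tumor_ml, schedule,
                                     sensitivity)
        idif <- add_tac_count_noise(idif_clean, cava_ml, schedule,
                                    sensitivity)
      } else {
        tumor <- tumor_clean; idif <- idif_clean
      }
      list(tumor = tumor, idif = idif, tumor_clean = tumor_clean,
           idif_clean = idif_clean, ki_true = ki_2tc(kin), kin = kin,
           tumor_ml = tumor_ml)
    })
  })
}

#' Effect sizes and calibration of the longitudinal cohort generator
#'
#' Defaults reproduce the observed study scale: weekly anatomic-volume
#' means near (177, 666, 936) mm^3 for weeks 3-5, metabolic volume
#' coupled linearly to anatomic volume, SUV coupled moderately to Ki,
#' ADC coupled negatively to volume, and treatment shifting endpoint
#' ADC up and volume/cell density down.
#'
#' @param vmri_week_means mean anatomic tumor volume (mm^3) weeks 3-5.
#' @param vmri_cv between-mouse CV of the week-3 volume.
#' @param growth_cv CV of the weekly growth factors.
#' @param mtv_intercept,mtv_slope,mtv_sd MTV ~ vMRI linear coupling (mm^3).
#' @param ki_mean,ki_cv,ki_range net-influx-constant sampling.
#' @param suv_intercept,suv_ki_slope,suv_sd SUVmean ~ Ki coupling.
#' @param suvmax_ratio,suvmax_ratio_sd SUVmax / SUVmean ratio.
#' @param adc_intercept,adc_vmri_slope,adc_sd,adc_range ADC ~ vMRI
#'   coupling (mm^2/s per mm^3).
#' @param density_mean,density_sd untreated cellular density (cells/mm^2).
#' @param endpoint_vmri_control,endpoint_vmri_cv_control control-arm
#'   endpoint volume (mm^3).
#' @param treated_vmri_mult,treated_vmri_cv treated endpoint volume
#'   multiplier (growth suppression) and CV.
#' @param treated_adc_mult treated ADC multiplier (> 1: normalization of
#'   restricted diffusion).
#' @param endpoint_adc_control,endpoint_adc_sd control endpoint ADC.
#' @param treated_adc_sd treated endpoint ADC spread.
#' @param treated_density_mult treated cell-density multiplier (< 1).
#' @param treated_density_sd treated density spread.
#' @return a list of class `cohort_effects`.
#' @export
cohort_effects <- function(vmri_week_means = c(177, 666, 936),
                           vmri_cv = 0.20, growth_cv = 0.15,
                           mtv_intercept = 111, mtv_slope = 0.586,
                           mtv_sd = 50,
                           ki_mean = 0.039, ki_cv = 0.22,
                           ki_range = c(0.015, 0.055),
                           suv_intercept = 1.2, suv_ki_slope = 22,
                           suv_sd = 0.25,
                           suvmax_ratio = 1.77, suvmax_ratio_sd = 0.08,
                           adc_intercept = 1.25e-3,
                           adc_vmri_slope = -1.5e-7, adc_sd = 1.0e-4,
                           adc_range = c(0.82e-3, 1.50e-3),
                           density_mean = 11300, density_sd = 350,
                           endpoint_vmri_control = 2245,
                           endpoint_vmri_cv_control = 0.30,
                           treated_vmri_mult = 0.35, treated_vmri_cv = 0.45,
                           treated_adc_mult = 1.2,
                           endpoint_adc_control = 1.0e-3,
                           endpoint_adc_sd = 0.6e-4,
                           treated_adc_sd = 0.8e-4,
                           treated_density_mult = 0.77,
                           treated_density_sd = 1000) {
  structure(as.list(environment()), class = "cohort_effects")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate the longitudinal imaging cohort table
#'
#' Emulates a weekly tumor-progression study plus a chemotherapy arm:
#' 18 mice followed by T2 MRI and dynamic PET over weeks 3-5 with the
#' scan design thinning as animals exit (14/10/8 T2 scans, 12/10/4 PET
#' scans, two week-4 scans static-only), and 9 treatment-study mice
#' (5 treated, 4 control) with endpoint DWI + histology at week 7/8.
#' One row per scan; marker columns are NA where that modality does not
#' measure them. Per-scan ground truth is attached as attribute `truth`.
#'
#' @param n_mice number of progression-phase mice (default 18).
#' @param arms named vector `c(treated = , control = )` (default 5 / 4).
#' @param effects a [cohort_effects()].
#' @param seed RNG seed.
#' @return a data.frame of class `cohort_table` with columns `scan_id`,
#'   `mouse_id`, `arm`, `week`, `phase`, `modality`, `static_only`,
#'   `vmri_mm3`, `adc_mean_mm2_s`, `suv_max`, `suv_mean`, `mtv_mm3`,
#'   `tlg`, `ki_ml_min_ml`, `mrfdg_umol_min_ml`, `density_cells_mm2`.
#' @export
simulate_cohort <- function(n_mice = 18L, arms = c(treated = 5L, control = 4L),
                            effects = cohort_effects(), seed = 42L) {
  stopifnot(inherits(effects, "cohort_effects"))
  e <- effects
  if (n_mice < 14L) stop("the progression design needs >= 14 mice")
  with_seed(seed, {
    # --- progression phase: latent weekly volumes per mouse ---
    v3 <- rlnorm_mean(n_mice, e$vmri_week_means[1], e$vmri_cv)
    g4 <- rlnorm_mean(n_mice, e$vmri_week_means[2] / e$vmri_week_means[1],
                      e$growth_cv)
    g5 <- rlnorm_mean(n_mice, e$vmri_week_means[3] / e$vmri_week_means[2],
                      e$growth_cv)
    vol <- cbind(v3, v3 * g4, v3 * g4 * g5)   # weeks 3, 4, 5
    t2_mice <- list(`3` = 1:14, `4` = 1:10, `5` = 1:8)
    pet_mice <- list(`3` = 1:12, `4` = 1:10, `5` = 1:4)
    static_only_mice <- c(9L, 10L)            # week-4 technical failures
    rows <- list()
    truth <- list()
    add_row <- function(...) {
      rows[[length(rows) + 1L]] <<- data.frame(...)
    }
    for (wk in 3:5) {
      wi <- wk - 2L
      for (m in t2_mice[[as.character(wk)]]) {
        add_row(mouse_id = sprintf("M%02d", m), arm = "naive", week = wk,
                phase = "progression", modality = "T2", static_only = FALSE,
                vmri_mm3 = vol[m, wi], adc_mean_mm2_s = NA_real_,
                suv_max = NA_real_, suv_mean = NA_real_, mtv_mm3 = NA_real_,
                tlg = NA_real_, ki_ml_min_ml = NA_real_,
                mrfdg_umol_min_ml = NA_real_,
                density_cells_mm2 = NA_real_)
      }
      for (m in pet_mice[[as.character(wk)]]) {
        mtv <- max(5, e$mtv_intercept + e$mtv_slope * vol[m, wi] +
                     rnorm(1, 0, e$mtv_sd))
        ki <- rlnorm_mean(1, e$ki_mean, e$ki_cv, e$ki_range[1],
                          e$ki_range[2])
        suv_mean <- clamp(e$suv_intercept + e$suv_ki_slope * ki +
                            rnorm(1, 0, e$suv_sd), 1.4, 2.9)
        suv_max <- suv_mean * (e$suvmax_ratio +
                                 rnorm(1, 0, e$suvmax_ratio_sd))
        st_only <- wk == 4L && m %in% static_only_mice
        add_row(mouse_id = sprintf("M%02d", m), arm = "naive", week = wk,
                phase = "progression", modality = "PET",
                static_only = st_only, vmri_mm3 = NA_real_,
                adc_mean_mm2_s = NA_real_, suv_max = suv_max,
                suv_mean = suv_mean, mtv_mm3 = mtv, tlg = suv_mean * mtv,
                ki_ml_min_ml = if (st_only) NA_real_ else ki,
                mrfdg_umol_min_ml = if (st_only) NA_real_ else ki * 10,
                density_cells_mm2 = NA_real_)
      }
    }
    # --- treatment study: endpoint DWI + histology, week 7/8 ---
    arm_of <- c(rep("treated", arms[["treated"]]),
                rep("control", arms[["control"]]))
    for (i in seq_along(arm_of)) {
      trt <- arm_of[i] == "treated"
      vm <- if (trt)
        rlnorm_mean(1, e$endpoint_vmri_control * e$treated_vmri_mult,
                    e$treated_vmri_cv)
      else rlnorm_mean(1, e$endpoint_vmri_control,
                       e$endpoint_vmri_cv_control)
      adc <- if (trt)
        rnorm(1, e$endpoint_adc_control * e$treated_adc_mult,
              e$treated_adc_sd)
      else rnorm(1, e$endpoint_adc_control, e$endpoint_adc_sd)
      dens <- if (trt)
        max(1000, rnorm(1, e$density_mean * e$treated_density_mult,
                        e$treated_density_sd))
      else max(1000, rnorm(1, e$density_mean, e$density_sd))
      add_row(mouse_id = sprintf("%s%d", if (trt) "T" else "C",
                                 if (trt) i else i - arms[["treated"]]),
              arm = arm_of[i], week = if (i %% 2 == 0) 8L else 7L,
              phase = "endpoint", modality = "DWI", static_only = FALSE,
              vmri_mm3 = vm, adc_mean_mm2_s = adc, suv_max = NA_real_,
              suv_mean = NA_real_, mtv_mm3 = NA_real_, tlg = NA_real_,
              ki_ml_min_ml = NA_real_, mrfdg_umol_min_ml = NA_real_,
              density_cells_mm2 = dens)
    }
    out <- do.call(rbind, rows)
    out <- cbind(scan_id = seq_len(nrow(out)), out)
    attr(out, "truth") <- list(weekly_volumes = vol, seed = seed,
                               effects = e)
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
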