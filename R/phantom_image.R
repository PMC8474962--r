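# Digital 4D PET phantom: voxelized anatomy (tumor, vena cava, kidneys,
# bladder), frame-averaged activity curves, Gaussian PSF blur and
# count-based Poisson noise, with full ground truth returned.

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# Poisson sampling that stays exact for small means and switches to the
# normal approximation where rpois would overflow integer range
safe_rpois <- function(lambda) {
  out <- numeric(length(lambda))
  small <- lambda < 1e6
  if (any(small)) out[small] <- rpois(sum(small), lambda[small])
  if (any(!small))
    out[!small] <- pmax(0, round(lambda[!small] +
                                   sqrt(lambda[!small]) * rnorm(sum(!small))))
  out
}

# world coordinates (mm) of voxel centers along each axis
axis_coords <- function(shape, spacing, origin = c(0, 0, 0)) {
  lapply(1:3, function(a) origin[a] + (seq_len(shape[a]) - 1) * spacing[a])
}

#' Ellipsoid mask on a voxel grid
#' @param shape grid dimensions.
#' @param spacing voxel spacing (mm).
#' @param center_mm,semi_mm ellipsoid center and semi-axes in world mm.
#' @param origin world origin (mm).
#' @return logical 3D array.
#' @export
ellipsoid_mask <- function(shape, spacing, center_mm, semi_mm,
                           origin = c(0, 0, 0)) {
  if (any(semi_mm <= 0)) stop("semi-axes must be > 0")
  co <- axis_coords(shape, spacing, origin)
  dx2 <- ((co[[1]] - center_mm[1]) / semi_mm[1])^2
  dy2 <- ((co[[2]] - center_mm[2]) / semi_mm[2])^2
  dz2 <- ((co[[3]] - center_mm[3]) / semi_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# axis-aligned cylinder along z
cylinder_mask <- function(shape, spacing, center_xy_mm, radius_mm, z_range_mm,
                          origin = c(0, 0, 0)) {
  co <- axis_coords(shape, spacing, origin)
  dx2 <- (co[[1]] - center_xy_mm[1])^2
  dy2 <- (co[[2]] - center_xy_mm[2])^2
  inxy <- outer(dx2, dy2, `+`) <= radius_mm^2
  inz <- co[[3]] >= z_range_mm[1] & co[[3]] <= z_range_mm[2]
  array(outer(inxy, inz, `&`), dim = shape)
}

#' Scene description for the dynamic PET phantom
#'
#' Geometry, point-spread function and noise model of the digital mouse
#' abdomen: an ellipsoidal tumor, a thin vena-cava cylinder carrying the
#' input function, two kidneys and a filling bladder (the structures a
#' fixed-threshold segmentation must exclude), over a low body background.
#' The default grid is 64^3 voxels of 0.4 mm. `sensitivity` converts
#' activity to expected counts (counts per Bq s); 0.08 approximates a
#' modern small-animal PET ring. The tumor carries a radial uptake
#' heterogeneity field normalized to mean 1 over the tumor so the
#' tumor-mean TAC stays exactly on the nominal kinetic curve.
#'
#' @param shape grid dimensions (default c(64, 64, 64)).
#' @param spacing_mm voxel spacing (default 0.4 mm isotropic).
#' @param tumor_center_mm,tumor_semiaxes_mm tumor ellipsoid (mm).
#' @param cava_center_xy_mm,cava_radius_mm,cava_z_mm vena-cava cylinder.
#' @param kidney_centers_mm list of two sphere centers (mm).
#' @param kidney_radius_mm kidney sphere radius.
#' @param bladder_center_mm,bladder_radius_mm bladder sphere.
#' @param psf_fwhm_mm Gaussian PSF FWHM (default 0.8 mm; 0 disables).
#' @param sensitivity counts per (Bq s) (default 0.08; 0 disables noise).
#' @param tumor_heterogeneity amplitude of the radial uptake field
#'   (default 0.35: core ~1.35x, rim ~0.85x the nominal curve).
#' @param background_kBq_ml late-time body background level.
#' @param seed RNG seed recorded in the scene and used for noise.
#' @return object of class `phantom_scene`.
#' @export
phantom_scene <- function(shape = c(64L, 64L, 64L),
                          spacing_mm = c(0.4, 0.4, 0.4),
                          tumor_center_mm = c(8, 13, 13),
                          tumor_semiaxes_mm = c(3.5, 3.0, 3.0),
                          cava_center_xy_mm = c(17, 8),
                          cava_radius_mm = 0.6,
                          cava_z_mm = c(3, 22),
                          kidney_centers_mm = list(c(20, 17, 8.5),
                                                   c(20, 17, 16.5)),
                          kidney_radius_mm = 2.0,
                          bladder_center_mm = c(6, 5, 20),
                          bladder_radius_mm = 2.4,
                          psf_fwhm_mm = 0.8,
                          sensitivity = 0.08,
                          tumor_heterogeneity = 0.35,
                          background_kBq_ml = 100,
                          seed = 42L) {
  shape <- as.integer(shape)
  if (any(shape < 1L)) stop("grid dimensions must be >= 1")
  if (any(spacing_mm <= 0)) stop("spacing must be > 0")
  if (any(tumor_semiaxes_mm <= 0)) stop("tumor semi-axes must be > 0")
  fov <- shape * spacing_mm
  inside <- function(p, r) all(p - r >= 0) && all(p + r <= fov)
  if (!inside(tumor_center_mm, tumor_semiaxes_mm))
    stop("tumor ellipsoid extends outside the grid")
  if (!inside(bladder_center_mm, bladder_radius_mm))
    stop("bladder extends outside the grid")
  for (k in kidney_centers_mm)
    if (!inside(k, kidney_radius_mm)) stop("kidney extends outside the grid")
  structure(list(shape = shape, spacing_mm = spacing_mm,
                 tumor_center_mm = tumor_center_mm,
                 tumor_semiaxes_mm = tumor_semiaxes_mm,
                 cava_center_xy_mm = cava_center_xy_mm,
                 cava_radius_mm = cava_radius_mm, cava_z_mm = cava_z_mm,
                 kidney_centers_mm = kidney_centers_mm,
                 kidney_radius_mm = kidney_radius_mm,
                 bladder_center_mm = bladder_center_mm,
                 bladder_radius_mm = bladder_radius_mm,
                 psf_fwhm_mm = psf_fwhm_mm, sensitivity = sensitivity,
                 tumor_heterogeneity = tumor_heterogeneity,
                 background_kBq_ml = background_kBq_ml, seed = seed),
            class = "phantom_scene")
}

#' Separable 3D Gaussian blur
#'
#' Convolves a 3D array with an axis-separable Gaussian kernel truncated
#' at 4 sigma, renormalized at the edges. Used as the phantom's
#' point-spread function.
#'
#' @param arr 3D numeric array.
#' @param sigma_vox Gaussian sigma per axis, in voxels (length 3).
#' @return blurred array of the same dimensions.
#' @export
blur3d <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 1e-6) next
    n <- d[ax]
    half <- max(1L, ceiling(4 * s))
    k <- seq(-half, half)
    G <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + k
      ok <- j >= 1 & j <= n
      w <- exp(-k[ok]^2 / (2 * s^2))
      G[i, j[ok]] <- w / sum(w)      # renormalize at edges
    }
    arr <- if (ax == 1) {
      array(G %*% matrix(arr, d[1]), d)
    } else if (ax == 2) {
      aperm(array(G %*% matrix(aperm(arr, c(2, 1, 3)), d[2]),
                  d[c(2, 1, 3)]), c(2, 1, 3))
    } else {
      aperm(array(G %*% matrix(aperm(arr, c(3, 1, 2)), d[3]),
                  d[c(3, 1, 2)]), c(2, 3, 1))
    }
  }
  arr
}

# frame-averaged structure curves on a schedule (kBq/ml)
structure_curves <- function(scene, aif, kin, schedule, dt_s = 0.1) {
  end_s <- max(schedule$starts_s + schedule$durations_s)
  t_min <- seq(0, by = dt_s / 60, length.out = ceiling(end_s / dt_s) + 1L)
  sol <- solve_2tc(aif, kin, t_min)
  t_s <- t_min * 60
  kid <- 0.35 * sol$cp + 420 * (1 - exp(-t_min / 8))
  bla <- 25 * t_min
  bg <- scene$background_kBq_ml * (1 - exp(-t_min / 5))
  list(tumor = frame_average(sol$ct, t_s, schedule),
       cava = frame_average(sol$cp, t_s, schedule),
       kidney = frame_average(kid, t_s, schedule),
       bladder = frame_average(bla, t_s, schedule),
       background = frame_average(bg, t_s, schedule))
}

#' Build a dynamic 4D PET phantom with known ground truth
#'
#' Voxelizes the scene structures, assigns each the frame-averaged
#' activity of its ground-truth curve (tumor: 2TC tissue curve scaled by
#' the normalized heterogeneity field; cava: the input function; kidneys
#' and bladder: excretion ramps; background: slow constant approach),
#' applies the Gaussian PSF, and adds Poisson noise on expected counts
#' `N = C * voxel_volume * frame_duration * sensitivity` back-converted
#' to concentration. Deterministic for a fixed scene seed.
#'
#' @param scene a [phantom_scene()].
#' @param aif [aif_params()] (the true input function).
#' @param kin [two_tc_params()] (the true tumor kinetics).
#' @param schedule a [frame_schedule()] (default the 1-h dynamic scheme).
#' @param noise logical; `FALSE` disables Poisson noise.
#' @param psf logical; `FALSE` disables the PSF blur.
#' @return list with `series` (a `dynamic_series`, kBq/ml), and `truth`:
#'   masks (`tumor`, `cava`, `kidneys`, `bladder`), `ki_true`, `cp_frames`
#'   (true input at frame resolution, a [tac()]), `tumor_tac` (true
#'   tumor-mean TAC, a [tac()]), `kin`, `aif`, `scene`.
#' @export
build_dynamic_phantom <- function(scene, aif = aif_params(),
                                  kin = two_tc_params(),
                                  schedule = dynamic_1h_schedule(),
                                  noise = TRUE, psf = TRUE) {
  stopifnot(inherits(scene, "phantom_scene"))
  sh <- scene$shape; sp <- scene$spacing_mm
  tumor <- ellipsoid_mask(sh, sp, scene$tumor_center_mm,
                          scene$tumor_semiaxes_mm)
  cava <- cylinder_mask(sh, sp, scene$cava_center_xy_mm,
                        scene$cava_radius_mm, scene$cava_z_mm)
  kidneys <- ellipsoid_mask(sh, sp, scene$kidney_centers_mm[[1]],
                            rep(scene$kidney_radius_mm, 3)) |
    ellipsoid_mask(sh, sp, scene$kidney_centers_mm[[2]],
                   rep(scene$kidney_radius_mm, 3))
  bladder <- ellipsoid_mask(sh, sp, scene$bladder_center_mm,
                            rep(scene$bladder_radius_mm, 3))
  structs <- list(tumor = tumor, cava = cava, kidneys = kidneys,
                  bladder = bladder)
  pairs <- combn(names(structs), 2)
  for (i in seq_len(ncol(pairs))) {
    ov <- sum(structs[[pairs[1, i]]] & structs[[pairs[2, i]]])
    if (ov > 0) stop("phantom structures overlap: ", pairs[1, i], " and ",
                     pairs[2, i], " share ", ov, " voxels")
  }
  # radial heterogeneity field over the tumor, normalized to mean 1
  het <- array(1, sh)
  if (scene$tumor_heterogeneity > 0 && any(tumor)) {
    co <- axis_coords(sh, sp)
    r2 <- outer(outer(((co[[1]] - scene$tumor_center_mm[1]) /
                         scene$tumor_semiaxes_mm[1])^2,
                      ((co[[2]] - scene$tumor_center_mm[2]) /
                         scene$tumor_semiaxes_mm[2])^2, `+`),
                ((co[[3]] - scene$tumor_center_mm[3]) /
                   scene$tumor_semiaxes_mm[3])^2, `+`)
    f <- 1 + scene$tumor_heterogeneity * (1 - 2 * r2)
    f <- pmax(f, 0.2)
    het[tumor] <- f[tumor] / mean(f[tumor])
  }
  curves <- structure_curves(scene, aif, kin, schedule)
  voxvol_ml <- prod(sp) * 1e-3
  sigma_vox <- if (psf && scene$psf_fwhm_mm > 0)
    rep(scene$psf_fwhm_mm / 2.3548, 3) / sp else c(0, 0, 0)
  mids <- mid_times(schedule, "min")
  frames <- vector("list", length(schedule))
  build_one <- function(i) {
    act <- array(curves$background[i], sh)
    act[tumor] <- curves$tumor[i] * het[tumor]
    act[cava] <- curves$cava[i]
    act[kidneys] <- curves$kidney[i]
    act[bladder] <- curves$bladder[i]
    if (any(sigma_vox > 0)) act <- blur3d(act, sigma_vox)
    act
  }
  arrs <- lapply(seq_along(frames), build_one)
  if (noise && scene$sensitivity > 0) {
    arrs <- with_seed(scene$seed, {
      lapply(seq_along(arrs), function(i) {
        f <- 1000 * voxvol_ml * schedule$durations_s[i] * scene$sensitivity
        array(safe_rpois(pmax(arrs[[i]], 0) * f) / f, sh)
      })
    })
  }
  frames <- lapply(arrs, image_volume, spacing = sp, units = "kBq_per_ml")
  series <- dynamic_series(frames, schedule)
  truth <- list(
    masks = lapply(structs, function(m)
      voi_mask(m, spacing = sp, label = "truth")),
    ki_true = ki_2tc(kin),
    cp_frames = tac(mids, curves$cava),
    tumor_tac = tac(mids, curves$tumor),
    kin = kin, aif = aif, scene = scene)
  list(series = series, truth = truth)
}

#' Average late frames into a static image
#'
#' Duration-weighted mean of all frames whose interval lies inside
#' `[t0_s, t1_s]` -- the standard late static reconstruction window.
#'
#' @param series a `dynamic_series`.
#' @param t0_s,t1_s window in seconds (default 1800-3600).
#' @return an `image_volume` in the series' units.
#' @export
static_from_dynamic <- function(series, t0_s = 1800, t1_s = 3600) {
  sch <- series$schedule
  sel <- which(sch$starts_s >= t0_s - 1e-9 &
                 sch$starts_s + sch$durations_s <= t1_s + 1e-9)
  if (!length(sel)) stop("no frames inside the static window")
  w <- sch$durations_s[sel] / sum(sch$durations_s[sel])
  acc <- array(0, dim(series$frames[[1]]$values))
  for (i in seq_along(sel)) acc <- acc + w[i] * series$frames[[sel[i]]]$values
  image_volume(acc, spacing = series$frames[[1]]$spacing,
               origin = series$frames[[1]]$origin,
               units = series$frames[[1]]$units)
}
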