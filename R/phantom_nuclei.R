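# Histology phantom: dark elliptical nuclei on a bright background at a
# prescribed cell density, with exact ground-truth count.

#' Build a synthetic nuclei image at a prescribed cell density
#'
#' Places exactly `round(density * field_mm2)` elliptical nuclei (dark on
#' bright, hematoxylin-like contrast) uniformly over a square field by
#' dart throwing with a minimum center separation of
#' `2 * radius_um * (1 - overlap_frac)`. The image is lightly blurred
#' (optics) and carries Gaussian intensity noise. The packing is checked
#' up front: densities whose exclusion discs would exceed ~45% area
#' coverage are refused as infeasible for random placement.
#'
#' @param density_cells_per_mm2 target density, > 0.
#' @param field_mm2 field area in mm^2 (square field, default 0.1).
#' @param radius_um mean nucleus radius in micrometers (default 2.6).
#' @param overlap_frac allowed fractional overlap of the joint radii in
#'   [0, 0.3]; 0 keeps every pair of nuclei disjoint.
#' @param seed RNG seed; the image is deterministic per seed.
#' @param pixel_size_um pixel size (default 0.5 um, ~20x scan).
#' @param noise_sd intensity noise SD on the [0, 1] scale.
#' @param radius_jitter relative spread of the per-axis radii (default
#'   0.15).
#' @param min_gap_um extra guaranteed edge-to-edge gap (um); use ~1 um to
#'   keep nuclei separated even after optical blur.
#' @return list with `image` (matrix in [0, 1], attribute
#'   `pixel_size_um`), `truth_count`, `density_true` (= count / area),
#'   `centers_um`, `pixel_size_um`, `field_mm2`.
#' @export
build_nuclei_image <- function(density_cells_per_mm2, field_mm2 = 0.1,
                               radius_um = 2.6, overlap_frac = 0.1,
                               seed = 1L, pixel_size_um = 0.5,
                               noise_sd = 0.03, radius_jitter = 0.15,
                               min_gap_um = 0) {
  if (density_cells_per_mm2 <= 0) stop("density must be > 0")
  if (overlap_frac < 0 || overlap_frac > 0.3)
    stop("overlap_frac must lie in [0, 0.3]")
  n <- as.integer(round(density_cells_per_mm2 * field_mm2))
  side_um <- sqrt(field_mm2) * 1000
  # random sequential placement saturates near 55% disc coverage
  excl <- 2 * radius_um * (1 - overlap_frac) + min_gap_um
  coverage <- n * pi * (excl / 2)^2 / side_um^2
  if (coverage > 0.45)
    stop("density ", density_cells_per_mm2, " cells/mm2 infeasible for ",
         "radius ", radius_um, " um at overlap_frac ", overlap_frac,
         " (exclusion coverage ", round(coverage, 2), " > 0.45)")
  npx <- ceiling(side_um / pixel_size_um)
  with_seed(seed, {
    # draw per-nucleus ellipse axes first so the separation rule can use
    # the actual sizes: centers closer than
    # (rmax_i + rmax_j) (1 - overlap_frac) + min_gap_um are rejected
    ax_a <- radius_um * runif(n, 1 - radius_jitter, 1 + radius_jitter)
    ax_b <- radius_um * runif(n, 1 - radius_jitter, 1 + radius_jitter)
    rot <- runif(n, 0, pi)
    rmax <- pmax(ax_a, ax_b)
    centers <- matrix(NA_real_, n, 2)
    placed <- 0L
    attempts <- 0L
    max_attempts <- 400L * n + 1000L
    while (placed < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      p <- runif(2, 0, side_um)
      lim <- (rmax[seq_len(placed)] + rmax[placed + 1L]) *
        (1 - overlap_frac) + min_gap_um
      if (placed == 0L ||
          min((centers[seq_len(placed), 1] - p[1])^2 +
                (centers[seq_len(placed), 2] - p[2])^2 - lim^2) >= 0) {
        placed <- placed + 1L
        centers[placed, ] <- p
      }
    }
    if (placed < n)
      stop("could not place ", n, " nuclei (packed ", placed,
           "); density infeasible in practice")
    img <- matrix(0.86, npx, npx)
    for (j in seq_len(n)) {
      a <- ax_a[j]
      b <- ax_b[j]
      th <- rot[j]
      cx <- centers[j, 1] / pixel_size_um
      cy <- centers[j, 2] / pixel_size_um
      r_px <- max(a, b) / pixel_size_um
      x0 <- max(1L, floor(cx - r_px)); x1 <- min(npx, ceiling(cx + r_px))
      y0 <- max(1L, floor(cy - r_px)); y1 <- min(npx, ceiling(cy + r_px))
      if (x1 < x0 || y1 < y0) next
      xs <- (x0:x1 - cx) * pixel_size_um
      ys <- (y0:y1 - cy) * pixel_size_um
      xr <- outer(xs, ys * 0, `+`) ; yr <- outer(xs * 0, ys, `+`)
      u <- (cos(th) * xr + sin(th) * yr) / a
      v <- (-sin(th) * xr + cos(th) * yr) / b
      inside <- (u^2 + v^2) <= 1
      blk <- img[x0:x1, y0:y1]
      blk[inside] <- 0.24
      img[x0:x1, y0:y1] <- blk
    }
    img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 1))
    img <- img + matrix(rnorm(length(img), 0, noise_sd), npx, npx)
    img <- pmin(pmax(img, 0), 1)
    attr(img, "pixel_size_um") <- pixel_size_um
    list(image = img, truth_count = n,
         density_true = n / field_mm2, centers_um = centers[seq_len(n), ,
                                                            drop = FALSE],
         pixel_size_um = pixel_size_um, field_mm2 = field_mm2)
  })
}
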