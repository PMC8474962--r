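# DWI phantom: mono-exponential diffusion signal with Rician noise and a
# known ADC ground-truth map.

#' Build a diffusion-weighted MRI phantom with known ADC
#'
#' Creates a multi-b-value stack `S_b = S0 * exp(-b * ADC)` on the DWI
#' acquisition grid (default 67 x 93 matrix, 0.3 x 0.3 mm in-plane, 1 mm
#' slices). The tumor ellipsoid carries a smooth radial ADC field whose
#' in-tumor mean equals `tumor_adc_mean` exactly; the surrounding tissue
#' background has a higher, uniform ADC. When `sigma > 0`, magnitude
#' (Rician) noise of that scale is added to every image.
#'
#' @param b_values s/mm^2; at least two values including 0.
#' @param s0 proton-density signal at b = 0 (arbitrary units).
#' @param sigma Rician noise scale in signal units (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @param shape,spacing_mm grid geometry.
#' @param tumor_center_mm,tumor_semiaxes_mm tumor ellipsoid (mm).
#' @param tumor_adc_mean mean tumor ADC in mm^2/s (default 1.07e-3).
#' @param adc_heterogeneity relative amplitude of the radial ADC field.
#' @param background_adc background tissue ADC (default 2.0e-3 mm^2/s).
#' @return list with `stack` (list of `list(b=, vol=)`), `truth_adc`
#'   (an `image_volume`, mm2_per_s), `tumor_mask` (a `voi_mask`).
#' @export
build_dwi_phantom <- function(b_values = c(0, 1000), s0 = 1000, sigma = 0,
                              seed = 1L,
                              shape = c(67L, 93L, 20L),
                              spacing_mm = c(0.3, 0.3, 1.0),
                              tumor_center_mm = c(10, 14, 10),
                              tumor_semiaxes_mm = c(4.5, 5.5, 4.0),
                              tumor_adc_mean = 1.07e-3,
                              adc_heterogeneity = 0.12,
                              background_adc = 2.0e-3) {
  if (length(b_values) < 2L || min(b_values) != 0)
    stop("need >= 2 b-values including b = 0")
  if (anyDuplicated(b_values)) stop("b-values must be distinct")
  if (sigma < 0) stop("sigma must be >= 0")
  if (tumor_adc_mean <= 0 || background_adc <= 0)
    stop("ADC values must be positive")
  shape <- as.integer(shape)
  tumor <- ellipsoid_mask(shape, spacing_mm, tumor_center_mm,
                          tumor_semiaxes_mm)
  if (!any(tumor)) stop("tumor ellipsoid misses the grid")
  adc <- array(background_adc, shape)
  co <- axis_coords(shape, spacing_mm)
  r2 <- outer(outer(((co[[1]] - tumor_center_mm[1]) / tumor_semiaxes_mm[1])^2,
                    ((co[[2]] - tumor_center_mm[2]) / tumor_semiaxes_mm[2])^2,
                    `+`),
              ((co[[3]] - tumor_center_mm[3]) / tumor_semiaxes_mm[3])^2, `+`)
  field <- 1 + adc_heterogeneity * (2 * r2 - 1)   # restricted core, freer rim
  field_t <- field[tumor]
  adc[tumor] <- tumor_adc_mean * field_t / mean(field_t)  # exact in-tumor mean
  if (any(adc < 0)) stop("ADC specification produced negative values")
  b_values <- sort(b_values)
  make_stack <- function() lapply(b_values, function(b) {
    S <- s0 * exp(-b * adc)
    if (sigma > 0) {
      n <- length(S)
      S <- sqrt((S + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
      S <- array(S, shape)
    }
    list(b = b, vol = image_volume(S, spacing = spacing_mm,
                                   units = "signal_au"))
  })
  stack <- if (sigma > 0) with_seed(seed, make_stack()) else make_stack()
  list(stack = stack,
       truth_adc = image_volume(adc, spacing = spacing_mm,
                                units = "mm2_per_s"),
       tumor_mask = voi_mask(tumor, label = "tumor", spacing = spacing_mm))
}
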