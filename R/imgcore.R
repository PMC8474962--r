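#' @importFrom stats rnorm rpois runif rlnorm quantile sd var cor lm coef
#'   pnorm pt shapiro.test median setNames complete.cases
#' @importFrom utils head tail write.csv read.csv combn
NULL

VALID_UNITS <- c("Bq_per_ml", "kBq_per_ml", "SUV", "signal_au", "mm2_per_s",
                 "unknown")

#' 3D image volume with voxel geometry and intensity units
#'
#' The basic spatial container used throughout the package: a 3D scalar
#' array together with its voxel spacing (mm), world origin (mm) and a
#' mandatory intensity-units tag. World coordinates are axis-aligned,
#' `world = origin + (index - 1) * spacing` with 1-based voxel indices at
#' voxel centers; no shear or rotation is modeled.
#'
#' @param values 3D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm, strictly positive.
#' @param origin numeric length-3, world coordinate of voxel (1,1,1) in mm.
#' @param units one of `"Bq_per_ml"`, `"kBq_per_ml"`, `"SUV"`,
#'   `"signal_au"`, `"mm2_per_s"`, `"unknown"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing, origin = c(0, 0, 0),
                         units = "unknown") {
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L)
    stop("image_volume requires a 3D array; got ", length(dim(values)),
         " dimensions (use dynamic_series for 4D data)")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("origin must have length 3")
  units <- match.arg(units, VALID_UNITS)
  structure(list(values = values, spacing = spacing, origin = origin,
                 units = units),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, spacing %s mm, units %s\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"), x$units))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$values)

#' Volume of one voxel in mm^3
#' @param vol an `image_volume`, `voi_mask`, or numeric length-3 spacing.
#' @return voxel volume in mm^3.
#' @export
voxel_volume <- function(vol) {
  sp <- if (is.numeric(vol)) vol else vol$spacing
  prod(sp)
}

#' PET frame timing schedule
#'
#' Frame start times and durations in seconds. Mid-times (used as the time
#' axis of time-activity curves) are `start + duration / 2`.
#'
#' @param starts_s frame start times (s), non-negative, strictly increasing.
#' @param durations_s frame durations (s), strictly positive.
#' @param contiguous logical; if `TRUE` (default) frames must tile the
#'   acquisition without gaps, i.e. `start[i+1] == start[i] + duration[i]`.
#' @return An object of class `frame_schedule`.
#' @export
frame_schedule <- function(starts_s, durations_s, contiguous = TRUE) {
  starts_s <- as.numeric(starts_s)
  durations_s <- as.numeric(durations_s)
  if (length(starts_s) != length(durations_s) || length(starts_s) < 1L)
    stop("starts and durations must be equal-length, non-empty")
  if (any(starts_s < 0)) stop("frame starts must be >= 0")
  if (any(diff(starts_s) <= 0)) stop("frame starts must be strictly increasing")
  if (any(durations_s <= 0)) stop("frame durations must be > 0")
  if (contiguous && length(starts_s) > 1L) {
    gaps <- abs(starts_s[-1L] - (head(starts_s, -1L) + head(durations_s, -1L)))
    if (any(gaps > 1e-6))
      stop("schedule declared contiguous but has gaps/overlaps at frame(s) ",
           paste(which(gaps > 1e-6), collapse = ", "))
  }
  structure(list(starts_s = starts_s, durations_s = durations_s,
                 contiguous = contiguous),
            class = "frame_schedule")
}

#' @export
length.frame_schedule <- function(x) length(x$starts_s)

#' Frame mid-times
#' @param schedule a `frame_schedule`.
#' @param unit `"s"` or `"min"`.
#' @return numeric vector of frame mid-times.
#' @export
mid_times <- function(schedule, unit = c("min", "s")) {
  unit <- match.arg(unit)
  m <- schedule$starts_s + schedule$durations_s / 2
  if (unit == "min") m / 60 else m
}

#' The 1-h dynamic FDG frame scheme
#'
#' 19 contiguous frames: 5 x 2 s, 5 x 10 s, 2 x 120 s, 3 x 300 s,
#' 4 x 600 s, totalling 3600 s.
#' @return a `frame_schedule` of length 19.
#' @export
dynamic_1h_schedule <- function() {
  durations <- c(rep(2, 5), rep(10, 5), rep(120, 2), rep(300, 3), rep(600, 4))
  frame_schedule(starts_s = cumsum(c(0, head(durations, -1L))),
                 durations_s = durations, contiguous = TRUE)
}

#' Dynamic image series
#'
#' An ordered list of congruent `image_volume` frames plus a
#' `frame_schedule` of matching length. All frames must share grid shape,
#' spacing, origin and units.
#'
#' @param frames list of `image_volume`, identical grids and units.
#' @param schedule `frame_schedule` with `length(schedule) == length(frames)`.
#' @return An object of class `dynamic_series`.
#' @export
dynamic_series <- function(frames, schedule) {
  if (!inherits(schedule, "frame_schedule")) stop("schedule must be a frame_schedule")
  if (!length(frames)) stop("frames must be non-empty")
  if (length(frames) != length(schedule))
    stop("frame count (", length(frames), ") != schedule length (",
         length(schedule), ")")
  ref <- frames[[1L]]
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!inherits(f, "image_volume")) stop("frame ", i, " is not an image_volume")
    if (!identical(dim(f$values), dim(ref$values)) ||
        max(abs(f$spacing - ref$spacing)) > 1e-9 ||
        !identical(f$units, ref$units))
      stop("frame ", i, " grid/units differ from frame 1")
  }
  structure(list(frames = frames, schedule = schedule),
            class = "dynamic_series")
}

#' @export
length.dynamic_series <- function(x) length(x$frames)

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("<dynamic_series> %d frames of %s, %.0f s total\n",
              length(x$frames), paste(dim(x$frames[[1]]$values), collapse = "x"),
              sum(x$schedule$durations_s)))
  invisible(x)
}

#' Volume-of-interest mask
#'
#' A boolean grid congruent to a reference `image_volume`. Empty masks are
#' allowed and flagged via the `empty` field.
#'
#' @param values logical (or 0/1) 3D array.
#' @param label short name, e.g. `"tumor"`, `"cava"`, `"exclusion"`.
#' @param spacing voxel spacing (mm); defaults taken from `reference`.
#' @param origin world origin (mm).
#' @param reference optional `image_volume` supplying geometry.
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(values, label = "roi", spacing = NULL, origin = NULL,
                     reference = NULL) {
  if (!is.null(reference)) {
    if (is.null(spacing)) spacing <- reference$spacing
    if (is.null(origin)) origin <- reference$origin
    if (!identical(dim(as.array(values)), dim(reference$values)))
      stop("mask shape does not match reference volume shape")
  }
  if (is.null(spacing)) stop("spacing required (directly or via reference)")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (is.null(origin)) origin <- c(0, 0, 0)
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  if (length(dim(values)) != 3L) stop("mask must be 3D")
  storage.mode(values) <- "logical"
  values[is.na(values)] <- FALSE
  structure(list(values = values, label = label,
                 spacing = spacing, origin = as.numeric(origin),
                 empty = !any(values)),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat(sprintf("<voi_mask> '%s' %s, %d voxels%s\n", x$label,
              paste(dim(x$values), collapse = "x"), sum(x$values),
              if (x$empty) " (EMPTY)" else ""))
  invisible(x)
}

#' Number of true voxels in a mask
#' @param mask a `voi_mask`.
#' @return integer count.
#' @export
mask_count <- function(mask) sum(mask$values)

#' Per-scan PET metadata
#'
#' @param injected_dose_MBq activity at injection time (MBq), > 0.
#' @param body_weight_g animal body weight (g), > 0.
#' @param blood_glucose_mmol_l blood glucose (mmol/l), > 0.
#' @param assay_time_offset_min minutes from dose assay to injection
#'   (positive: assayed before injection).
#' @param mouse_id,week,arm cohort bookkeeping fields.
#' @return An object of class `scan_meta`.
#' @export
scan_meta <- function(injected_dose_MBq, body_weight_g,
                      blood_glucose_mmol_l = 6.0,
                      assay_time_offset_min = 0,
                      mouse_id = NA_character_, week = NA_integer_,
                      arm = NA_character_) {
  if (!is.finite(injected_dose_MBq) || injected_dose_MBq <= 0)
    stop("injected dose must be > 0")
  if (!is.finite(body_weight_g) || body_weight_g <= 0)
    stop("body weight must be > 0")
  if (!is.finite(blood_glucose_mmol_l) || blood_glucose_mmol_l <= 0)
    stop("blood glucose must be > 0")
  structure(list(injected_dose_MBq = injected_dose_MBq,
                 body_weight_g = body_weight_g,
                 blood_glucose_mmol_l = blood_glucose_mmol_l,
                 assay_time_offset_min = assay_time_offset_min,
                 mouse_id = mouse_id, week = week, arm = arm),
            class = "scan_meta")
}

#' Time-activity curve
#'
#' Mean regional concentration per frame versus frame mid-time.
#'
#' @param mid_min frame mid-times in minutes.
#' @param conc mean concentration per frame (kBq/ml unless noted).
#' @param units concentration units tag.
#' @return An object of class `tac` (a data-frame-like list).
#' @export
tac <- function(mid_min, conc, units = "kBq_per_ml") {
  if (length(mid_min) != length(conc)) stop("time/value length mismatch")
  if (any(diff(mid_min) <= 0)) stop("mid-times must be strictly increasing")
  structure(list(mid_min = as.numeric(mid_min), conc = as.numeric(conc),
                 units = units),
            class = "tac")
}

#' @export
length.tac <- function(x) length(x$mid_min)

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(mid_min = x$mid_min, conc = x$conc)
}

# --- spacing normalization -------------------------------------------------

# NIfTI pixdim entries are stored with signs in some vendor exports; spacing
# is defined strictly positive, with flipped axes recorded.
normalize_spacing <- function(raw) {
  raw <- as.numeric(raw)
  if (any(!is.finite(raw)) || any(raw == 0))
    stop("non-finite or zero spacing in header")
  list(spacing = abs(raw), flipped = raw < 0)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

# --- NIfTI readers/writers -------------------------------------------------

#' Write an image volume to NIfTI-1
#'
#' Writes `vol$values` with its spacing into a `.nii`/`.nii.gz` file plus a
#' JSON sidecar (`<stem>.json`) holding units and world origin. Masks are
#' written as uint8 0/1 via [write_mask()].
#'
#' @param vol an `image_volume`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(units = vol$units, origin = vol$origin),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a 3D image volume from NIfTI-1
#'
#' Units and origin are taken from the JSON sidecar written by
#' [write_volume()] when present; otherwise units are flagged `"unknown"`
#' and the origin is zero. Negative header spacings are normalized to
#' positive values with the flipped axes recorded in attribute
#' `flipped_axes`.
#'
#' @param path a `.nii`/`.nii.gz` file containing a 3D image.
#' @return an `image_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path,
                                           "': ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4L] > 1L)
    stop("'", path, "' is a 4D series; use read_dynamic()")
  if (length(d) == 4L) {
    img <- array(img, dim = d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) stop("expected a 3D volume, got ", length(d), "D")
  ns <- normalize_spacing(RNifti::pixdim(img)[1:3])
  units <- "unknown"; origin <- c(0, 0, 0)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$units) && meta$units %in% VALID_UNITS) units <- meta$units
    if (!is.null(meta$origin)) origin <- as.numeric(meta$origin)
  }
  out <- image_volume(array(as.numeric(img), dim = d), spacing = ns$spacing,
                      origin = origin, units = units)
  attr(out, "flipped_axes") <- ns$flipped
  out
}

#' Write a VOI mask as uint8 NIfTI
#' @param mask a `voi_mask`.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voi_mask"))
  v <- array(as.integer(mask$values), dim = dim(mask$values))
  img <- RNifti::asNifti(v, datatype = "uint8")
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(label = mask$label, origin = mask$origin),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a VOI mask from NIfTI
#' @param path mask file (any nonzero voxel is inside).
#' @return a `voi_mask`.
#' @export
read_mask <- function(path) {
  vol <- read_volume(path)
  label <- "roi"
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$label)) label <- meta$label
  }
  voi_mask(vol$values != 0, label = label, spacing = vol$spacing,
           origin = vol$origin)
}

#' Write a dynamic series as 4D NIfTI + schedule CSV
#' @param series a `dynamic_series`.
#' @param path output `.nii`/`.nii.gz` path.
#' @param schedule_path output CSV path (`frame,start_s,duration_s`).
#' @return `path`, invisibly.
#' @export
write_dynamic <- function(series, path, schedule_path) {
  stopifnot(inherits(series, "dynamic_series"))
  d <- dim(series$frames[[1]]$values)
  arr <- array(0, dim = c(d, length(series)))
  for (i in seq_along(series$frames)) arr[, , , i] <- series$frames[[i]]$values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$frames[[1]]$spacing, 1)
  RNifti::writeNifti(img, path)
  sch <- series$schedule
  write.csv(data.frame(frame = seq_along(sch$starts_s),
                       start_s = sch$starts_s, duration_s = sch$durations_s),
            schedule_path, row.names = FALSE)
  jsonlite::write_json(list(units = series$frames[[1]]$units,
                            origin = series$frames[[1]]$origin),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dynamic series from a 4D NIfTI plus a frame-schedule CSV
#'
#' The schedule CSV must have columns `frame,start_s,duration_s`; rows may
#' appear in any order and are sorted by start time. The frame count of the
#' image and the schedule must agree.
#'
#' @param path 4D `.nii`/`.nii.gz` file.
#' @param schedule_path schedule CSV.
#' @param contiguous logical, passed to [frame_schedule()].
#' @return a `dynamic_series`.
#' @export
read_dynamic <- function(path, schedule_path, contiguous = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 3L) d <- c(d, 1L)
  if (length(d) != 4L) stop("expected a 4D series, got ", length(dim(img)), "D")
  sch <- read.csv(schedule_path)
  need <- c("frame", "start_s", "duration_s")
  if (!all(need %in% names(sch)))
    stop("schedule CSV must have columns ", paste(need, collapse = ","))
  sch <- sch[order(sch$start_s), , drop = FALSE]
  if (nrow(sch) != d[4L])
    stop("frame-count mismatch: image has ", d[4L], " frames, schedule ",
         nrow(sch), " rows")
  schedule <- frame_schedule(sch$start_s, sch$duration_s,
                             contiguous = contiguous)
  ns <- normalize_spacing(RNifti::pixdim(img)[1:3])
  units <- "unknown"; origin <- c(0, 0, 0)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$units) && meta$units %in% VALID_UNITS) units <- meta$units
    if (!is.null(meta$origin)) origin <- as.numeric(meta$origin)
  }
  arr <- array(as.numeric(img), dim = d)
  frames <- lapply(seq_len(d[4L]), function(i)
    image_volume(arr[, , , i, drop = TRUE], spacing = ns$spacing,
                 origin = origin, units = units))
  dynamic_series(frames, schedule)
}

# --- mask resampling -------------------------------------------------------

#' Nearest-neighbour resampling of a mask onto a target grid
#'
#' For each target voxel center, the world coordinate is mapped into the
#' mask's own grid and the nearest source voxel decides membership. MRI and
#' PET grids in one study differ, so masks drawn on one modality must be
#' carried to the other through world coordinates before quantification.
#'
#' @param mask a `voi_mask` with its own spacing/origin.
#' @param target an `image_volume` defining the output grid.
#' @return a `voi_mask` on the target grid. Disjoint fields of view yield
#'   an empty mask with a warning.
#' @export
resample_mask_to <- function(mask, target) {
  stopifnot(inherits(mask, "voi_mask"), inherits(target, "image_volume"))
  dt <- dim(target$values)
  same_grid <- identical(dt, dim(mask$values)) &&
    max(abs(mask$spacing - target$spacing)) < 1e-9 &&
    max(abs(mask$origin - target$origin)) < 1e-9
  if (same_grid)
    return(voi_mask(mask$values, label = mask$label, reference = target))
  if (mask$empty) {
    return(voi_mask(array(FALSE, dt), label = mask$label, reference = target))
  }
  # world coords of target voxel centers, per axis
  idx <- lapply(1:3, function(a) {
    w <- target$origin[a] + (seq_len(dt[a]) - 1) * target$spacing[a]
    i <- round((w - mask$origin[a]) / mask$spacing[a]) + 1
    i[i < 1 | i > dim(mask$values)[a]] <- NA_integer_
    as.integer(i)
  })
  out <- array(FALSE, dt)
  ok1 <- !is.na(idx[[1]]); ok2 <- !is.na(idx[[2]]); ok3 <- !is.na(idx[[3]])
  if (any(ok1) && any(ok2) && any(ok3)) {
    sub <- mask$values[idx[[1]][ok1], idx[[2]][ok2], idx[[3]][ok3], drop = FALSE]
    out[which(ok1), which(ok2), which(ok3)] <- sub
  }
  res <- voi_mask(out, label = mask$label, reference = target)
  if (res$empty)
    warning("resampled mask '", mask$label,
            "' is empty (disjoint fields of view?)")
  res
}
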