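#' Synthetic dynamic renogram phantoms
#'
#' The phantom emulates a pediatric 99mTc-MAG3 dynamic renal acquisition:
#' two elliptical kidneys whose size grows with patient age, a filling
#' bladder, and a spatially uniform background, sampled frame by frame as
#' independent Poisson counts. Defaults mirror the clinical protocol of a
#' 20-minute acquisition of 120 frames of 10 s at 128 x 128 pixels.
#'
#' @name phantom
NULL

# Kidney semi-axis anchors (pixels, on a 128-pixel grid) at ages 0 and 17.
# Linearly interpolated in between; scaled proportionally for other image
# sizes.
.KIDNEY_AXES_AGE0  <- c(8, 5.5)
.KIDNEY_AXES_AGE17 <- c(15, 10)

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so phantom sampling never perturbs user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Create a phantom specification
#'
#' Draws per-study anatomy and kinetics for a synthetic renogram. For a
#' fixed `(seed, patient_age_years)` pair the spec is fully deterministic.
#' Kidney semi-axes interpolate linearly between age-0 and age-17 anchors,
#' so organ size grows monotonically with age.
#'
#' @param seed Integer seed; threaded through both spec generation and
#'   later Poisson sampling.
#' @param patient_age_years Age in years, 0 to 17.
#' @param image_size Image side in pixels (square grid).
#' @param background_level Mean background counts per pixel per frame at
#'   the 100% count level.
#' @param kidney_peak_amplitude Mean excess counts per pixel per frame at
#'   the peak of the kidney time-activity curve.
#' @return An object of class `phantom_spec`.
#' @export
make_phantom_spec <- function(seed, patient_age_years,
                              image_size = 128L,
                              background_level = 0.5,
                              kidney_peak_amplitude = 6) {
  if (!is.numeric(patient_age_years) || length(patient_age_years) != 1 ||
      is.na(patient_age_years) || patient_age_years < 0 || patient_age_years > 17)
    stop("patient_age_years must be a single number in [0, 17]")
  if (image_size < 32) stop("image_size must be at least 32 pixels")
  stopifnot(background_level > 0, kidney_peak_amplitude > 0)
  seed <- as.integer(seed)

  s <- image_size / 128
  frac <- patient_age_years / 17
  axes <- (.KIDNEY_AXES_AGE0 + frac * (.KIDNEY_AXES_AGE17 - .KIDNEY_AXES_AGE0)) * s

  with_seed(seed, {
    # mild per-study anatomical jitter (pixels)
    jit <- stats::runif(6, -2, 2) * s
    centers <- list(
      left  = c(row = 0.42 * image_size + jit[1], col = 0.32 * image_size + jit[2]),
      right = c(row = 0.42 * image_size + jit[3], col = 0.68 * image_size + jit[4])
    )
    bladder_center <- c(row = 0.82 * image_size + jit[5], col = 0.50 * image_size + jit[6])
    bladder_radius <- (5 + 2 * frac) * s

    # per-kidney kinetics: MAG3-like uptake peaking around 3-5 min,
    # then washout. Shape parameter alpha = washout * peak_time keeps
    # the maximum exactly at peak_time_s.
    curve_params <- lapply(c("left", "right"), function(k) {
      peak  <- stats::runif(1, 180, 300)              # s
      wash  <- stats::runif(1, 1 / 600, 1 / 300)      # 1/s
      amp   <- kidney_peak_amplitude * stats::runif(1, 0.85, 1.15)
      list(peak_time_s = peak, washout_rate = wash,
           uptake_shape = wash * peak, amplitude = amp)
    })
    names(curve_params) <- c("left", "right")

    spec <- list(
      image_size = as.integer(image_size),
      kidney_centers = centers,
      kidney_axes = axes,          # c(semi_row, semi_col)
      bladder_center = bladder_center,
      bladder_radius = bladder_radius,
      background_level = background_level,
      kidney_peak_amplitude = kidney_peak_amplitude,
      curve_params = curve_params,
      patient_age_years = patient_age_years,
      seed = seed
    )
    class(spec) <- "phantom_spec"
    validate_phantom_spec(spec)
    spec
  })
}

validate_phantom_spec <- function(spec) {
  sz <- spec$image_size
  for (side in c("left", "right")) {
    ctr <- spec$kidney_centers[[side]]
    if (any(ctr - spec$kidney_axes < 1) || any(ctr + spec$kidney_axes > sz))
      stop("kidney ellipse extends outside the image")
  }
  bc <- spec$bladder_center
  if (any(bc - spec$bladder_radius < 1) || any(bc + spec$bladder_radius > sz))
    stop("bladder disk extends outside the image")
  stopifnot(spec$background_level > 0, spec$kidney_peak_amplitude > 0,
            all(spec$kidney_axes > 0))
  masks <- kidney_masks(spec)
  if (any(masks$left & masks$right)) stop("kidney masks overlap")
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Synthetic renogram phantom spec\n")
  cat(sprintf("  image: %d x %d px, patient age %.1f y, seed %d\n",
              x$image_size, x$image_size, x$patient_age_years, x$seed))
  cat(sprintf("  kidney semi-axes: %.1f x %.1f px\n",
              x$kidney_axes[1], x$kidney_axes[2]))
  cat(sprintf("  background %.3g cts/px/frame, kidney peak ~%.3g cts/px/frame\n",
              x$background_level, x$kidney_peak_amplitude))
  invisible(x)
}

# Normalized squared elliptical radius for every pixel: <= 1 inside.
ellipse_r2 <- function(size, center, axes) {
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((rows - center["row"]) / axes[1])^2 + ((cols - center["col"]) / axes[2])^2
}

kidney_masks <- function(spec, scale = 1) {
  sz <- spec$image_size
  ax <- spec$kidney_axes * scale
  list(
    left  = ellipse_r2(sz, spec$kidney_centers$left,  ax) <= 1,
    right = ellipse_r2(sz, spec$kidney_centers$right, ax) <= 1
  )
}

bladder_mask <- function(spec) {
  sz <- spec$image_size
  ellipse_r2(sz, spec$bladder_center, rep(spec$bladder_radius, 2)) <= 1
}

#' Kidney time-activity curve
#'
#' Relative activity (peak = 1) of one kidney at time `t_seconds`:
#' a gamma-variate uptake phase with exponential washout,
#' `(t/tp)^a * exp(a - b t)` with `a = b * tp`, anchored at 0 for `t = 0`
#' and peaking exactly at the configured peak time `tp`.
#'
#' @param spec A `phantom_spec`.
#' @param t_seconds Time(s) since injection, seconds (vectorized).
#' @param side `"left"` or `"right"`.
#' @return Relative activity values, unitless and non-negative.
#' @export
time_activity_curve <- function(spec, t_seconds, side = c("left", "right")) {
  side <- match.arg(side)
  if (any(t_seconds < 0)) stop("t_seconds must be non-negative")
  p <- spec$curve_params[[side]]
  tp <- p$peak_time_s; a <- p$uptake_shape; b <- p$washout_rate
  v <- ifelse(t_seconds == 0, 0, (t_seconds / tp)^a * exp(a - b * t_seconds))
  pmax(v, 0)
}

# Bladder filling: rises towards a plateau as the tracer is excreted.
bladder_curve <- function(spec, t_seconds) {
  1 - exp(-t_seconds / 500)
}

#' Expected (noise-free) counts of one frame
#'
#' Mean counts per pixel at time `t_seconds` at the 100% count level:
#' `background_level` everywhere, plus per-kidney
#' `amplitude * time_activity_curve(t)` on the kidney ellipses and a
#' bladder-filling term on the bladder disk.
#'
#' @inheritParams time_activity_curve
#' @return A numeric `image_size x image_size` matrix of expected counts.
#' @export
render_mean_frame <- function(spec, t_seconds) {
  stopifnot(length(t_seconds) == 1, t_seconds >= 0)
  sz <- spec$image_size
  img <- matrix(spec$background_level, sz, sz)
  masks <- kidney_masks(spec)
  for (side in c("left", "right")) {
    amp <- spec$curve_params[[side]]$amplitude
    img[masks[[side]]] <- img[masks[[side]]] +
      amp * time_activity_curve(spec, t_seconds, side)
  }
  bm <- bladder_mask(spec)
  img[bm] <- img[bm] +
    0.7 * spec$kidney_peak_amplitude * bladder_curve(spec, t_seconds)
  img
}

#' Sample a dynamic study from a phantom
#'
#' Draws every pixel of every frame from a Poisson law with mean
#' `count_scale * render_mean_frame(spec, t_mid)` where `t_mid` is the
#' frame mid-time. `count_scale = 0.5` emulates a study acquired at half
#' the administered activity. Sampling is seeded from the spec's seed, so
#' the same spec always yields the same counts.
#'
#' @param spec A `phantom_spec`.
#' @param count_scale Multiplier on expected counts, in (0, 1].
#' @param n_frames Number of frames (default 120).
#' @param frame_duration_s Frame duration in seconds (default 10).
#' @return A `dynamic_study`: list with `frames` (n_frames x H x W integer
#'   array), `frame_duration_s`, `patient_age_years`, `study_id`,
#'   `provenance`.
#' @export
sample_study <- function(spec, count_scale = 1, n_frames = 120L,
                         frame_duration_s = 10) {
  if (count_scale <= 0 || count_scale > 1)
    stop("count_scale must be in (0, 1]")
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1) stop("n_frames must be a positive integer")
  stopifnot(frame_duration_s > 0)
  sz <- spec$image_size
  frames <- array(0L, dim = c(n_frames, sz, sz))
  with_seed(spec$seed + 1L, {
    for (i in seq_len(n_frames)) {
      t_mid <- (i - 0.5) * frame_duration_s
      mu <- count_scale * render_mean_frame(spec, t_mid)
      frames[i, , ] <- stats::rpois(sz * sz, as.vector(mu))
    }
  })
  study <- list(
    frames = frames,
    frame_duration_s = frame_duration_s,
    patient_age_years = spec$patient_age_years,
    study_id = sprintf("synthetic-%08d-age%04.1f", spec$seed, spec$patient_age_years),
    provenance = "synthetic",
    count_scale = count_scale,
    seed = spec$seed
  )
  class(study) <- "dynamic_study"
  study
}

#' @export
print.dynamic_study <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Dynamic renal study '%s' (%s)\n", x$study_id, x$provenance))
  cat(sprintf("  %d frames of %g s (%g min total), %d x %d px\n",
              d[1], x$frame_duration_s, d[1] * x$frame_duration_s / 60,
              d[2], d[3]))
  cat(sprintf("  total counts %.4g, patient age %.1f y\n",
              sum(x$frames), x$patient_age_years))
  invisible(x)
}

#' Ground-truth regions of interest for a phantom
#'
#' Kidney ROIs are exactly the phantom kidney ellipses. The background ROI
#' is an annulus around each kidney, separated from the organ by
#' `margin_pixels` and of width `width_pixels`, excluding both kidneys and
#' the bladder.
#'
#' @param spec A `phantom_spec`.
#' @param margin_pixels Gap between kidney edge and background annulus.
#' @param width_pixels Radial width of the background annulus.
#' @return An `roi_set`: list of logical masks `left_kidney`,
#'   `right_kidney`, `background`.
#' @export
ground_truth_rois <- function(spec, margin_pixels = 2L, width_pixels = 4L) {
  if (margin_pixels < 0) stop("margin_pixels must be >= 0")
  masks <- kidney_masks(spec)
  bm <- bladder_mask(spec)
  ax_min <- min(spec$kidney_axes)
  inner <- 1 + margin_pixels / ax_min
  outer <- 1 + (margin_pixels + width_pixels) / ax_min
  bg <- matrix(FALSE, spec$image_size, spec$image_size)
  for (side in c("left", "right")) {
    r2 <- ellipse_r2(spec$image_size, spec$kidney_centers[[side]], spec$kidney_axes)
    bg <- bg | (r2 > inner^2 & r2 <= outer^2)
  }
  bg <- bg & !masks$left & !masks$right & !bm
  if (!any(bg))
    stop("degenerate ROI: background annulus is empty for this margin")
  rois <- list(left_kidney = masks$left, right_kidney = masks$right,
               background = bg)
  class(rois) <- "roi_set"
  validate_roi_set(rois)
  rois
}

validate_roi_set <- function(rois) {
  stopifnot(inherits(rois, "roi_set") || is.list(rois))
  for (nm in c("left_kidney", "right_kidney", "background")) {
    if (is.null(rois[[nm]]) || !any(rois[[nm]]))
      stop("degenerate ROI: mask '", nm, "' is empty")
  }
  if (any(rois$left_kidney & rois$right_kidney))
    stop("ROI invariant violated: kidney masks overlap")
  if (any(rois$background & (rois$left_kidney | rois$right_kidney)))
    stop("ROI invariant violated: background overlaps a kidney mask")
  invisible(rois)
}
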