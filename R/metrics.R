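#' Image-quality metrics
#'
#' Kidney-ROI signal-to-noise ratio and multiscale structural similarity,
#' the two quantities used to judge denoising quality, plus per-image
#' metric reports and a gain/loss summary across methods.
#'
#' @name quality_metrics
NULL

#' ROI statistics of an image
#'
#' @param image Numeric matrix.
#' @param lesion_mask,background_mask Logical masks of the same shape.
#' @return List with `mu_L` (lesion mean), `mu_B` (background mean) and
#'   `sigma_B` (population standard deviation of the background).
#' @export
roi_stats <- function(image, lesion_mask, background_mask) {
  stopifnot(is.matrix(image))
  if (!identical(dim(image), dim(lesion_mask)) ||
      !identical(dim(image), dim(background_mask)))
    stop("mask shape does not match image")
  if (!any(lesion_mask) || !any(background_mask))
    stop("degenerate ROI: empty mask")
  bg <- image[background_mask]
  list(mu_L = mean(image[lesion_mask]),
       mu_B = mean(bg),
       sigma_B = sqrt(mean((bg - mean(bg))^2)))
}

#' Signal-to-noise ratio from ROI statistics
#'
#' `SNR = (mu_L - mu_B) / sigma_B`. Invariant under positive affine
#' intensity transforms of the image.
#'
#' @param stats List as returned by [roi_stats()].
#' @return Unitless SNR.
#' @export
snr <- function(stats) {
  if (stats$sigma_B <= 0)
    stop("undefined SNR: background standard deviation is zero")
  (stats$mu_L - stats$mu_B) / stats$sigma_B
}

#' Kidney SNR of an image given an ROI set
#'
#' @param image Numeric matrix.
#' @param rois An `roi_set` (masks are resampled if their size differs
#'   from the image).
#' @param side `"left"` or `"right"`.
#' @return Unitless SNR for that kidney.
#' @export
kidney_snr <- function(image, rois, side = c("left", "right")) {
  side <- match.arg(side)
  rois <- resize_rois(rois, nrow(image))
  lesion <- if (side == "left") rois$left_kidney else rois$right_kidney
  snr(roi_stats(image, lesion, rois$background))
}

resize_rois <- function(rois, size) {
  if (nrow(rois$left_kidney) == size) return(rois)
  rs <- function(m) resize_bilinear(m * 1, size, size) >= 0.5
  out <- list(left_kidney = rs(rois$left_kidney),
              right_kidney = rs(rois$right_kidney),
              background = rs(rois$background))
  out$background <- out$background & !out$left_kidney & !out$right_kidney
  class(out) <- "roi_set"
  validate_roi_set(out)
  out
}

#' MS-SSIM parameters
#'
#' Defaults follow the canonical five-scale setting: per-scale weights
#' (0.0448, 0.2856, 0.3001, 0.2363, 0.1333) applied equally to the
#' luminance (coarsest scale only), contrast and structure exponents, an
#' 11 x 11 Gaussian window with sigma 1.5, and stabilizing constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` with dynamic range `L = 1` for
#' normalized images.
#'
#' @param scales Number of dyadic scales M.
#' @param weights Per-scale exponent weights (length `scales`, sum 1).
#' @param window_size Odd Gaussian window size.
#' @param window_sigma Gaussian window sigma.
#' @param K1,K2 Stabilizing constants relative to the dynamic range.
#' @param L Dynamic range of the images.
#' @param strict If `TRUE`, images too small for `scales` raise an error;
#'   otherwise the scale count is reduced with a warning and the weights
#'   renormalized.
#' @return An `msssim_params` list.
#' @export
msssim_params <- function(scales = 5L,
                          weights = c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333),
                          window_size = 11L, window_sigma = 1.5,
                          K1 = 0.01, K2 = 0.03, L = 1, strict = FALSE) {
  stopifnot(scales >= 1, length(weights) == scales,
            window_size %% 2 == 1, window_sigma > 0)
  weights <- weights / sum(weights)
  structure(list(scales = as.integer(scales), weights = weights,
                 window_size = as.integer(window_size),
                 window_sigma = window_sigma, K1 = K1, K2 = K2, L = L,
                 strict = strict),
            class = "msssim_params")
}

gauss_window <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# Separable valid-mode filtering: band matrix times image times band'.
filter_valid <- function(x, g) {
  n <- length(g)
  H <- nrow(x); W <- ncol(x)
  Ah <- matrix(0, H - n + 1, H)
  for (i in seq_len(H - n + 1)) Ah[i, i:(i + n - 1)] <- g
  if (W == H) Aw <- Ah else {
    Aw <- matrix(0, W - n + 1, W)
    for (i in seq_len(W - n + 1)) Aw[i, i:(i + n - 1)] <- g
  }
  Ah %*% x %*% t(Aw)
}

downsample2 <- function(x) {
  H <- 2 * (nrow(x) %/% 2); W <- 2 * (ncol(x) %/% 2)
  x <- x[seq_len(H), seq_len(W), drop = FALSE]
  0.25 * (x[seq(1, H, 2), seq(1, W, 2), drop = FALSE] +
          x[seq(2, H, 2), seq(1, W, 2), drop = FALSE] +
          x[seq(1, H, 2), seq(2, W, 2), drop = FALSE] +
          x[seq(2, H, 2), seq(2, W, 2), drop = FALSE])
}

#' Multiscale structural similarity
#'
#' Combines a luminance term at the coarsest scale with contrast and
#' structure terms at every dyadic scale, each raised to its scale
#' weight. Symmetric in its two arguments; equals 1 for identical
#' images. For non-negative normalized inputs the value lies in
#' \[0, 1\]; structure terms are not clamped, so pathological inputs can
#' in principle yield negative components.
#'
#' @param x,y Numeric matrices of identical shape.
#' @param params An [msssim_params()].
#' @return The MS-SSIM value.
#' @export
ms_ssim <- function(x, y, params = msssim_params()) {
  if (!identical(dim(x), dim(y))) stop("images must have the same shape")
  side <- min(dim(x))
  max_m <- max(1L, floor(log2(side / params$window_size)) + 1L)
  M <- params$scales
  if (max_m < M) {
    if (params$strict)
      stop("image too small for ", M, " scales (max ", max_m, ")")
    warning("reducing MS-SSIM scales from ", M, " to ", max_m,
            " for image side ", side)
    M <- max_m
  }
  w <- params$weights[seq_len(M)]
  w <- w / sum(w)
  C1 <- (params$K1 * params$L)^2
  C2 <- (params$K2 * params$L)^2
  g <- gauss_window(params$window_size, params$window_sigma)

  val <- 1
  for (j in seq_len(M)) {
    mux <- filter_valid(x, g); muy <- filter_valid(y, g)
    sx2 <- filter_valid(x * x, g) - mux * mux
    sy2 <- filter_valid(y * y, g) - muy * muy
    sxy <- filter_valid(x * y, g) - mux * muy
    sx2[sx2 < 0] <- 0; sy2[sy2 < 0] <- 0
    sx <- sqrt(sx2); sy <- sqrt(sy2)
    cj <- (2 * sx * sy + C2) / (sx2 + sy2 + C2)
    sj <- (sxy + C2 / 2) / (sx * sy + C2 / 2)
    val <- val * mean(cj)^w[j] * mean(sj)^w[j]
    if (j == M) {
      lj <- (2 * mux * muy + C1) / (mux * mux + muy * muy + C1)
      val <- val * mean(lj)^w[j]
    } else {
      x <- downsample2(x); y <- downsample2(y)
    }
  }
  val
}

#' Evaluate a denoising method on paired test images
#'
#' For each pair, computes left/right kidney SNR of the denoised image
#' and the MS-SSIM between the denoised image and the full-count
#' reference; the un-denoised low-count input provides the comparison
#' baseline.
#'
#' @param denoised List of denoised image matrices, parallel to `pairs`.
#' @param pairs List of `paired_sample` objects.
#' @param params MS-SSIM parameters.
#' @param method Label stored in the report.
#' @return A data frame (one row per image) with columns `study_id`,
#'   `age`, `method`, `snr_left`, `snr_right`, `ms_ssim`, and the
#'   baseline columns `snr_left_orig`, `snr_right_orig`, `ms_ssim_orig`.
#' @export
evaluate_method <- function(denoised, pairs, params = msssim_params(),
                            method = "denoised") {
  stopifnot(length(denoised) == length(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (is.null(p$rois)) {
      warning("skipping ", p$study_id, ": missing ROI")
      return(NULL)
    }
    img <- denoised[[i]]
    ts <- nrow(img)
    ref <- preprocess(p$reference_image, ts)
    inp <- preprocess(p$input_image, ts)
    data.frame(
      study_id = p$study_id,
      age = p$patient_age_years,
      method = method,
      snr_left = kidney_snr(img, p$rois, "left"),
      snr_right = kidney_snr(img, p$rois, "right"),
      ms_ssim = suppressWarnings(ms_ssim(img, ref, params)),
      snr_left_orig = kidney_snr(inp, p$rois, "left"),
      snr_right_orig = kidney_snr(inp, p$rois, "right"),
      ms_ssim_orig = suppressWarnings(ms_ssim(inp, ref, params)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Gain/loss summary across methods
#'
#' For each metric and method, the signed mean percentage change versus
#' the un-denoised baseline, normalized (as in the relative-error
#' definition) by the larger of the two values: positive entries are
#' gains, negative entries losses.
#'
#' @param reports A data frame from [evaluate_method()] (several methods
#'   may be row-bound together).
#' @return A data frame with one row per metric and one column per method.
#' @export
metrics_summary <- function(reports) {
  signed_change <- function(a, b) 100 * mean((a - b) / pmax(abs(a), abs(b)))
  methods <- unique(reports$method)
  out <- data.frame(metric = c("snr_right", "snr_left", "ms_ssim"))
  for (m in methods) {
    r <- reports[reports$method == m, ]
    out[[m]] <- c(signed_change(r$snr_right, r$snr_right_orig),
                  signed_change(r$snr_left, r$snr_left_orig),
                  signed_change(r$ms_ssim, r$ms_ssim_orig))
  }
  out
}
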