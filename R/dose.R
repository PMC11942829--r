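#' Dose-reduction simulation by partial frame summation
#'
#' In clinical practice the final static renogram image is the sum of all
#' acquired frames. Summing only a fraction of the frames simulates a
#' proportional reduction of the administered activity, since expected
#' counts scale linearly with both dose and acquisition time.
#'
#' @name dose_simulation
NULL

#' Sum a fraction of the frames of a dynamic study
#'
#' @param study A `dynamic_study`.
#' @param fraction Fraction of frames to sum, in (0, 1]. The number of
#'   frames used is `round(fraction * n_frames)`.
#' @param scheme How the frame subset is chosen: `"alternating"` (every
#'   other frame, preserving the full temporal envelope of the renogram),
#'   `"first_block"` (a leading block), or `"random"` (seeded by the
#'   study seed).
#' @return A `summed_image`: list with `pixels` (H x W matrix),
#'   `count_fraction`, `study_id`, `patient_age_years`, `frame_indices`.
#' @export
sum_frames <- function(study, fraction = 1,
                       scheme = c("alternating", "first_block", "random")) {
  scheme <- match.arg(scheme)
  if (fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  n <- dim(study$frames)[1]
  m <- round(fraction * n)
  if (m < 1) stop("fraction selects no frames")
  idx <- switch(scheme,
    # evenly spaced over the whole acquisition; step >= 1 keeps the
    # floors strictly increasing, so indices are always unique
    alternating = if (m == 1) 1L else floor(seq(0, n - 1, length.out = m)) + 1,
    first_block = seq_len(m),
    random = with_seed(if (is.null(study$seed)) 0L else study$seed + 2L,
                       sort(sample.int(n, m)))
  )
  idx <- unique(as.integer(idx))
  stopifnot(length(idx) == m, all(idx >= 1 & idx <= n))
  px <- apply(study$frames[idx, , , drop = FALSE], c(2, 3), sum)
  out <- list(pixels = px, count_fraction = fraction,
              study_id = study$study_id,
              patient_age_years = study$patient_age_years,
              frame_indices = idx)
  class(out) <- "summed_image"
  out
}

#' @export
print.summed_image <- function(x, ...) {
  cat(sprintf("Summed renogram image '%s': %d x %d px, %d frames (%.0f%% counts)\n",
              x$study_id, nrow(x$pixels), ncol(x$pixels),
              length(x$frame_indices), 100 * x$count_fraction))
  invisible(x)
}

#' Preprocess a summed image for the networks
#'
#' Resizes to `target_size` x `target_size` (bilinear; no interpolation is
#' applied when the image is already at the target size) and rescales
#' intensities to `[0, 1]` by dividing by the image maximum. An all-zero
#' image is returned unchanged (all zeros), not treated as an error.
#'
#' @param image A `summed_image` or a plain numeric matrix.
#' @param target_size Output side length in pixels.
#' @return A numeric matrix in `[0, 1]` of size `target_size^2`.
#' @export
preprocess <- function(image, target_size = 128L) {
  px <- if (inherits(image, "summed_image")) image$pixels else image
  if (!is.matrix(px) || length(px) == 0) stop("image must be a non-empty matrix")
  if (nrow(px) != target_size || ncol(px) != target_size)
    px <- resize_bilinear(px, target_size, target_size)
  mx <- max(px)
  if (mx > 0) px <- px / mx
  px
}

# Plain bilinear resampling on the pixel-center grid.
resize_bilinear <- function(px, h, w) {
  H <- nrow(px); W <- ncol(px)
  rf <- (seq_len(h) - 0.5) * H / h + 0.5 - 0.5  # source row coordinate
  cf <- (seq_len(w) - 0.5) * W / w + 0.5 - 0.5
  r0 <- pmin(pmax(floor(rf), 1), H); r1 <- pmin(r0 + 1, H)
  c0 <- pmin(pmax(floor(cf), 1), W); c1 <- pmin(c0 + 1, W)
  ar <- pmin(pmax(rf - r0, 0), 1); ac <- pmin(pmax(cf - c0, 0), 1)
  top <- px[r0, c0, drop = FALSE] * outer(1 - ar, 1 - ac) +
         px[r0, c1, drop = FALSE] * outer(1 - ar, ac)
  bot <- px[r1, c0, drop = FALSE] * outer(ar, 1 - ac) +
         px[r1, c1, drop = FALSE] * outer(ar, ac)
  top + bot
}

#' Build the paired low-count/full-count dataset
#'
#' For each study, sums `fractions[1]` (reference) and `fractions[2]`
#' (input) of the frames, producing one paired sample per study and an
#' inventory of `2 * n_studies` images.
#'
#' @param studies A list of study records: each element either a
#'   `dynamic_study` or a list with fields `study` and `rois`.
#' @param rois Either `NULL` (each record must carry its own `rois`) or a
#'   list of `roi_set` objects parallel to `studies`.
#' @param scheme Frame-subset scheme passed to [sum_frames()].
#' @param fractions Length-2 vector `(reference, input)` count fractions.
#' @return A list with `pairs` (list of `paired_sample`) and
#'   `n_images` (the image inventory count).
#' @export
build_dataset <- function(studies, rois = NULL,
                          scheme = "alternating", fractions = c(1.0, 0.5)) {
  if (length(studies) < 1) stop("need at least one study")
  stopifnot(length(fractions) == 2)
  pairs <- vector("list", length(studies))
  for (i in seq_along(studies)) {
    rec <- studies[[i]]
    if (inherits(rec, "dynamic_study")) {
      study <- rec
      roi <- if (!is.null(rois)) rois[[i]] else NULL
    } else {
      study <- rec$study
      roi <- if (!is.null(rec$rois)) rec$rois else if (!is.null(rois)) rois[[i]] else NULL
    }
    if (is.null(roi))
      stop("configuration error: study ", study$study_id, " has no ROIs")
    ref <- sum_frames(study, fractions[1], scheme)
    inp <- sum_frames(study, fractions[2], scheme)
    p <- list(input_image = inp, reference_image = ref, rois = roi,
              study_id = study$study_id,
              patient_age_years = study$patient_age_years,
              split = NA_character_)
    class(p) <- "paired_sample"
    pairs[[i]] <- p
  }
  list(pairs = pairs, n_images = 2L * length(studies))
}

#' Assign train/validation/test splits
#'
#' Splits by study (a study never straddles splits). Counts follow the
#' published accounting over individual images: train and validation get
#' `round(n * fraction)` items and the remainder goes to test, which for
#' 200 images at fractions (0.67, 0.16, 0.17) yields 134/32/34.
#'
#' @param items A list of `paired_sample` objects (or anything with a
#'   `study_id`); one item per study.
#' @param fractions Length-3 numeric `(train, val, test)` summing to 1.
#' @param seed Integer seed for the shuffling.
#' @return The items with `$split` set; attribute `"counts"` holds the
#'   per-split image counts (2 images per item).
#' @export
split_dataset <- function(items, fractions = c(0.67, 0.16, 0.17), seed = 1L) {
  n <- length(items)
  if (n < 3) stop("need at least as many items as splits")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n_train <- as.integer(round(n * fractions[1]))
  n_val <- as.integer(round(n * fractions[2]))
  n_test <- n - n_train - n_val
  # guarantee every split at least one item (possible since n >= 3):
  # borrow from the largest split
  while (min(n_train, n_val, n_test) < 1) {
    big <- which.max(c(n_train, n_val, n_test))
    small <- which.min(c(n_train, n_val, n_test))
    delta <- c(0L, 0L, 0L); delta[big] <- -1L; delta[small] <- 1L
    n_train <- n_train + delta[1]; n_val <- n_val + delta[2]
    n_test <- n_test + delta[3]
  }
  ord <- with_seed(as.integer(seed), sample.int(n))
  lab <- character(n)
  lab[ord[seq_len(n_train)]] <- "train"
  lab[ord[n_train + seq_len(n_val)]] <- "val"
  lab[ord[n_train + n_val + seq_len(n_test)]] <- "test"
  for (i in seq_len(n)) items[[i]]$split <- lab[i]
  attr(items, "counts") <- c(train = 2L * n_train, val = 2L * n_val,
                             test = 2L * n_test)
  items
}
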