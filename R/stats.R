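#' Paired statistical comparison of denoising methods
#'
#' Per-image metrics of two methods are compared with a paired two-tailed
#' test: a t-test when the paired differences look normal (Shapiro-Wilk
#' at alpha = 0.05), a Wilcoxon signed-rank test otherwise, mirroring the
#' usual practice in image-quality studies. No multiplicity correction is
#' applied by default; a Holm-corrected view is available.
#'
#' @name evaluation_stats
NULL

#' Choose the paired test for a difference vector
#'
#' @param differences Numeric vector of paired differences (n >= 3).
#' @param alpha Normality-test level.
#' @return `"t"` or `"wilcoxon"`; all-zero differences return
#'   `"degenerate"`.
#' @export
choose_test <- function(differences, alpha = 0.05) {
  if (length(differences) < 3) stop("need at least 3 paired differences")
  if (all(differences == 0)) return("degenerate")
  sw <- stats::shapiro.test(differences)
  if (sw$p.value >= alpha) "t" else "wilcoxon"
}

#' Compare two paired metric vectors
#'
#' Runs the test chosen by [choose_test()] on `a - b` and returns the
#' two-tailed p-value. The signed-rank test uses the exact distribution
#' for n <= 25 without ties and the continuity-corrected normal
#' approximation otherwise; zero differences are dropped (the standard
#' signed-rank convention).
#'
#' @param a,b Numeric vectors of equal length (n >= 3).
#' @param method_a,method_b Labels for the report.
#' @param metric Metric label.
#' @return A `paired_comparison` list with `p_value`, `test_used`, `n`,
#'   and a `degenerate` flag (identical samples: no test run, p = NA).
#' @export
paired_compare <- function(a, b, method_a = "a", method_b = "b",
                           metric = "metric") {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 3) stop("need at least 3 pairs")
  d <- a - b
  test <- choose_test(d)
  if (test == "degenerate") {
    out <- list(method_a = method_a, method_b = method_b, metric = metric,
                test_used = "none", p_value = NA_real_, n = length(d),
                degenerate = TRUE)
    class(out) <- "paired_comparison"
    return(out)
  }
  p <- if (test == "t") {
    stats::t.test(d)$p.value
  } else {
    nz <- d[d != 0]
    exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
    suppressWarnings(stats::wilcox.test(nz, exact = exact,
                                        correct = TRUE)$p.value)
  }
  out <- list(method_a = method_a, method_b = method_b, metric = metric,
              test_used = test, p_value = p, n = length(d),
              degenerate = FALSE)
  class(out) <- "paired_comparison"
  out
}

#' @export
print.paired_comparison <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("%s vs %s (%s): identical samples, no test run\n",
                x$method_a, x$method_b, x$metric))
  } else {
    cat(sprintf("%s vs %s (%s): %s test, p = %.4g (n = %d)%s\n",
                x$method_a, x$method_b, x$metric, x$test_used, x$p_value,
                x$n, if (x$p_value < 0.05) " *" else ""))
  }
  invisible(x)
}

#' Pairwise p-value matrix across methods
#'
#' One paired comparison per unordered pair of methods, reported as an
#' upper-triangular matrix with a parallel significance-flag matrix at
#' p < 0.05. No multiple-testing correction unless `correct = "holm"`.
#'
#' @param metric_values Named list: one numeric vector of per-image
#'   metric values per method, all aligned and of equal length.
#' @param metric Metric label.
#' @param correct `"none"` (default) or `"holm"`.
#' @return List with `p` (upper-triangular matrix, NA elsewhere),
#'   `significant` (logical matrix), and `comparisons`.
#' @export
pairwise_table <- function(metric_values, metric = "metric",
                           correct = c("none", "holm")) {
  correct <- match.arg(correct)
  methods <- names(metric_values)
  if (length(methods) < 2) stop("need at least 2 methods")
  lens <- vapply(metric_values, length, integer(1))
  if (length(unique(lens)) != 1) stop("metric vectors must be aligned")
  k <- length(methods)
  p <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  comps <- list()
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      cmp <- paired_compare(metric_values[[i]], metric_values[[j]],
                            methods[i], methods[j], metric)
      p[i, j] <- cmp$p_value
      comps[[length(comps) + 1]] <- cmp
    }
  }
  if (correct == "holm") {
    idx <- which(!is.na(p))
    p[idx] <- stats::p.adjust(p[idx], method = "holm")
  }
  list(p = p, significant = !is.na(p) & p < 0.05, comparisons = comps)
}

#' Age-stratified metric summary
#'
#' Groups per-image reports into age bands `[0, w)`, `[w, 2w)`, ... up to
#' 17 years and summarizes each metric per method and band.
#'
#' @param reports Data frame from [evaluate_method()] with an `age`
#'   column.
#' @param group_width_years Band width in years.
#' @return Data frame with one row per (method, age group) and mean and
#'   standard deviation of each metric; empty groups are absent.
#' @export
age_group_summary <- function(reports, group_width_years = 5L) {
  if (is.null(reports$age) || any(is.na(reports$age)))
    stop("every report row needs an age")
  w <- group_width_years
  breaks <- unique(c(seq(0, 17, by = w), 17 + 1e-9))
  grp <- cut(reports$age, breaks = breaks, right = FALSE,
             include.lowest = TRUE)
  agg <- function(v) c(mean = mean(v), sd = stats::sd(v))
  sp <- split(reports, list(reports$method, grp), drop = TRUE)
  rows <- lapply(sp, function(r) {
    band <- cut(r$age[1], breaks = breaks, right = FALSE,
                include.lowest = TRUE)
    data.frame(method = r$method[1],
               age_group = as.character(band),
               band_order = as.integer(band),
               n = nrow(r),
               snr_left_mean = mean(r$snr_left), snr_left_sd = stats::sd(r$snr_left),
               snr_right_mean = mean(r$snr_right), snr_right_sd = stats::sd(r$snr_right),
               ms_ssim_mean = mean(r$ms_ssim), ms_ssim_sd = stats::sd(r$ms_ssim),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$method, out$band_order), ]
  out$band_order <- NULL
  rownames(out) <- NULL
  out
}
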