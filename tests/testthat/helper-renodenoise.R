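# Shared fixtures for the suite: small, fast synthetic studies.
library(renodenoise)
rn <- asNamespace("renodenoise")

# A compact study (32 px, 40 frames) for tests that only need plumbing.
small_study <- function(seed = 11, age = 6, size = 32L, n_frames = 40L) {
  spec <- make_phantom_spec(seed, age, image_size = size)
  list(study = sample_study(spec, 1, n_frames = n_frames),
       rois = ground_truth_rois(spec), spec = spec)
}

small_pairs <- function(n = 6, seed = 20, size = 32L, n_frames = 40L,
                        split = c(0.5, 0.25, 0.25)) {
  studies <- lapply(seq_len(n), function(i)
    small_study(seed + i, age = (i %% 17) + 0.5, size = size,
                n_frames = n_frames))
  ds <- build_dataset(studies)
  split_dataset(ds$pairs, split, seed = seed)
}

# Deterministic image pair shared with the frozen external-oracle values
# in test-metrics.R.
oracle_images <- function() {
  set.seed(90210)
  n <- 64
  xg <- outer(seq(0, 1, length.out = n), seq(0, 1, length.out = n),
              function(a, b) 0.5 + 0.3 * sin(6 * a) * cos(4 * b))
  x <- pmin(pmax(xg + matrix(rnorm(n * n, 0, 0.02), n, n), 0), 1)
  y <- pmin(pmax(xg + matrix(rnorm(n * n, 0, 0.06), n, n), 0), 1)
  list(x = round(x, 10), y = round(y, 10))
}
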