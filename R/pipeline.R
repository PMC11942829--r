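#' End-to-end study pipeline
#'
#' Orchestrates the whole experiment from one configuration: simulate
#' synthetic studies, build and split the paired dataset, train the
#' requested denoisers, evaluate metrics, and run the pairwise
#' statistics, writing every artifact into a run directory. Stages are
#' idempotent: a stage whose output already exists under the same
#' configuration hash is skipped on rerun.
#'
#' @name cli_pipeline
NULL

#' Build and validate a pipeline configuration
#'
#' @param n_studies Number of synthetic studies.
#' @param image_size Phantom image side (pixels).
#' @param n_frames,frame_duration_s Acquisition protocol.
#' @param fractions Count fractions `(reference, input)`.
#' @param scheme Frame-subset scheme.
#' @param split_fractions Train/val/test fractions.
#' @param families Denoiser families to train.
#' @param epochs,batch_size,learning_rate,optimizer Training settings.
#' @param target_size Network input side.
#' @param seed Global seed.
#' @param outdir Run directory.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(n_studies = 8L, image_size = 64L,
                            n_frames = 120L, frame_duration_s = 10,
                            fractions = c(1.0, 0.5),
                            scheme = "alternating",
                            split_fractions = c(0.67, 0.16, 0.17),
                            families = "udncnn",
                            epochs = 20L, batch_size = 4L,
                            learning_rate = 1e-3, optimizer = "adam",
                            target_size = image_size, seed = 1L,
                            outdir = tempfile("renodenoise-run-")) {
  ok_fam <- c("dncnn", "udncnn", "dudncnn", "attngan")
  if (!all(families %in% ok_fam))
    stop("schema error: unknown model family: ",
         paste(setdiff(families, ok_fam), collapse = ", "))
  if (n_studies < 3) stop("schema error: need at least 3 studies to split")
  if (abs(sum(split_fractions) - 1) > 1e-9)
    stop("schema error: split fractions must sum to 1")
  if (!scheme %in% c("alternating", "first_block", "random"))
    stop("schema error: unknown scheme ", scheme)
  cfg <- list(n_studies = as.integer(n_studies),
              image_size = as.integer(image_size),
              n_frames = as.integer(n_frames),
              frame_duration_s = frame_duration_s,
              fractions = fractions, scheme = scheme,
              split_fractions = split_fractions,
              families = families, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size),
              learning_rate = learning_rate, optimizer = optimizer,
              target_size = as.integer(target_size),
              seed = as.integer(seed), outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with fields of [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

config_hash <- function(cfg) {
  s <- paste(utils::capture.output(utils::str(unclass(
    cfg[setdiff(names(cfg), "outdir")]))), collapse = "\n")
  # small rolling hash; stable across sessions
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%d", h)
}

stage_done <- function(dir, stage, hash) {
  f <- file.path(dir, paste0(".stage_", stage))
  file.exists(f) && identical(readLines(f, warn = FALSE)[1], hash)
}

mark_stage <- function(dir, stage, hash) {
  writeLines(hash, file.path(dir, paste0(".stage_", stage)))
}

#' Run the full pipeline
#'
#' Stages run in order simulate, prepare, train, evaluate, stats. Each
#' stage caches its output in the run directory; rerunning with the same
#' configuration reuses cached artifacts. A failure stops with the stage
#' name; completed stage outputs are retained.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the run directory, the metric reports,
#'   the summary table and the p-value tables.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, out_files, fun) {
    if (stage_done(config$outdir, name, hash) &&
        all(file.exists(file.path(config$outdir, out_files)))) {
      say("[%s] cached", name)
      return(invisible(FALSE))
    }
    say("[%s] running", name)
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    mark_stage(config$outdir, name, hash)
    invisible(TRUE)
  }

  jsonlite::write_json(c(unclass(config), list(config_hash = hash)),
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  studies_rds <- "studies.rds"
  stage("simulate", studies_rds, function() {
    ages <- with_seed(config$seed, stats::runif(config$n_studies, 0, 17))
    studies <- lapply(seq_len(config$n_studies), function(i) {
      spec <- make_phantom_spec(config$seed + i, ages[i],
                                image_size = config$image_size)
      list(study = sample_study(spec, 1, config$n_frames,
                                config$frame_duration_s),
           rois = ground_truth_rois(spec))
    })
    saveRDS(studies, file.path(config$outdir, studies_rds))
  })
  studies <- readRDS(file.path(config$outdir, studies_rds))

  pairs_rds <- "pairs.rds"
  stage("prepare", c(pairs_rds, "dataset.csv"), function() {
    ds <- build_dataset(studies, scheme = config$scheme,
                        fractions = config$fractions)
    pairs <- split_dataset(ds$pairs, config$split_fractions, config$seed)
    saveRDS(pairs, file.path(config$outdir, pairs_rds))
    man <- data.frame(
      study_id = vapply(pairs, function(p) p$study_id, character(1)),
      age = vapply(pairs, function(p) p$patient_age_years, numeric(1)),
      split = vapply(pairs, function(p) p$split, character(1)))
    utils::write.csv(man, file.path(config$outdir, "dataset.csv"),
                     row.names = FALSE)
  })
  pairs <- readRDS(file.path(config$outdir, pairs_rds))

  fit_files <- paste0("fit_", config$families, ".rds")
  stage("train", fit_files, function() {
    for (fam in config$families) {
      say("  training %s (%d epochs)", fam, config$epochs)
      tc <- training_config(batch_size = config$batch_size,
                            learning_rate = config$learning_rate,
                            optimizer = config$optimizer,
                            epochs = config$epochs, seed = config$seed,
                            allow_any = TRUE)
      fit <- fit_denoiser(pairs, fam, tc, target_size = config$target_size)
      saveRDS(fit, file.path(config$outdir, paste0("fit_", fam, ".rds")))
      utils::write.csv(fit$history,
                       file.path(config$outdir, paste0("loss_", fam, ".csv")),
                       row.names = FALSE)
    }
  })

  stage("evaluate", c("metrics.csv", "summary.csv"), function() {
    test <- pairs[vapply(pairs, function(p) p$split == "test", logical(1))]
    reports <- list()
    orig <- lapply(test, function(p) preprocess(p$input_image, config$target_size))
    reports$original <- evaluate_method(orig, test, method = "original")
    for (fam in config$families) {
      fit <- readRDS(file.path(config$outdir, paste0("fit_", fam, ".rds")))
      den <- predict(fit, test)
      reports[[fam]] <- evaluate_method(den, test, method = fam)
    }
    allr <- do.call(rbind, reports)
    utils::write.csv(allr, file.path(config$outdir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(metrics_summary(allr),
                     file.path(config$outdir, "summary.csv"),
                     row.names = FALSE)
  })
  reports <- utils::read.csv(file.path(config$outdir, "metrics.csv"))

  pv_files <- paste0("pvalues_", c("snr_right", "snr_left", "ms_ssim"), ".csv")
  stage("stats", pv_files, function() {
    for (metric in c("snr_right", "snr_left", "ms_ssim")) {
      vals <- split(reports[[metric]], reports$method)
      vals <- vals[c("original", intersect(config$families, names(vals)))]
      if (length(vals) >= 2 && length(vals[[1]]) >= 3) {
        tab <- pairwise_table(vals, metric)
        utils::write.csv(tab$p,
                         file.path(config$outdir,
                                   paste0("pvalues_", metric, ".csv")))
      } else {
        utils::write.csv(data.frame(),
                         file.path(config$outdir,
                                   paste0("pvalues_", metric, ".csv")))
      }
    }
  })

  res <- list(outdir = config$outdir, reports = reports,
              summary = utils::read.csv(file.path(config$outdir, "summary.csv")),
              pvalue_files = file.path(config$outdir, pv_files))
  say("pipeline complete: %s", config$outdir)
  invisible(res)
}
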