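# End-to-end workflow: generate -> split -> train -> predict -> evaluate,
# driven by one JSON config and one global seed so a run is reproducible
# from its config alone.

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir run directory (created; artifacts, logs, reports inside).
#' @param scene [scene_params()] for the synthetic dataset.
#' @param model [model_spec()].
#' @param train [train_spec()].
#' @param n_scenes number of scenes to generate.
#' @param eval_fraction fraction of scenes held out as a test set (never seen
#'   in training), evaluated with micro aggregation.
#' @param seed global seed; overrides the seeds in `scene` and `train`.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, scene = scene_params(), model = model_spec(),
                       train = train_spec(), n_scenes = 24L,
                       eval_fraction = 0.25, seed = 1L) {
  if (n_scenes < 4L) stop("`n_scenes` must be >= 4", call. = FALSE)
  if (eval_fraction <= 0 || eval_fraction >= 1)
    stop("`eval_fraction` must be in (0, 1)", call. = FALSE)
  structure(list(out_dir = out_dir, scene = scene, model = model,
                 train = train, n_scenes = as.integer(n_scenes),
                 eval_fraction = eval_fraction, seed = as.integer(seed)),
            class = "run_config")
}

#' Execute the full pipeline
#'
#' Generates the dataset, splits off a test set, trains the model, writes
#' checkpoints (final and best-validation-F1), predicts and evaluates on the
#' test set, and records a run manifest (config, seed, artifact checksums).
#'
#' @param config a [run_config()].
#' @param verbose print progress.
#' @return list with `fit`, `report` (test-set `metrics_report`), `manifest`
#'   (dataset manifest), `dir` (run directory).
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (!inherits(config, "run_config")) stop("`config` must come from run_config()", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sp <- config$scene; sp$seed <- config$seed
  ts <- config$train; ts$seed <- config$seed
  data_dir <- file.path(config$out_dir, "data")
  manifest <- generate_dataset(sp, config$n_scenes, data_dir)
  n_test <- max(1L, round(config$n_scenes * config$eval_fraction))
  test_idx <- with_seed(config$seed + 777L, sample.int(config$n_scenes, n_test))
  test_manifest <- manifest[sort(test_idx), , drop = FALSE]
  train_manifest <- manifest[-test_idx, , drop = FALSE]
  fit <- fit_rootseg(train_manifest, spec = config$model, control = ts,
                     verbose = verbose)
  ck_final <- file.path(config$out_dir, "model_final.rds")
  save_model(fit$model, ck_final)
  best <- fit$model; best$params <- fit$best_params
  ck_best <- file.path(config$out_dir, "model_best.rds")
  save_model(best, ck_best)
  write.csv(fit$history, file.path(config$out_dir, "training_log.csv"),
            row.names = FALSE)
  report <- evaluate_model(fit$model, test_manifest)
  jsonlite::write_json(
    list(accuracy = report$accuracy, precision = report$precision,
         recall = report$recall, f1 = report$f1, dice = report$dice,
         n_images = report$n_images),
    file.path(config$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  run_manifest <- list(
    seed = config$seed,
    n_scenes = config$n_scenes,
    n_test = n_test,
    config_hash = .config_hash(config),
    checkpoints = list(final = ck_final, best = ck_best),
    checksums = list(final = .file_checksum(ck_final),
                     best = .file_checksum(ck_best)))
  jsonlite::write_json(run_manifest, file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE)
  list(fit = fit, report = report, manifest = manifest, dir = config$out_dir)
}

.config_hash <- function(config) {
  s <- jsonlite::toJSON(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x), auto_unbox = TRUE)
  # tiny polynomial rolling hash; avoids a digest dependency
  .roll_hash(utf8ToInt(as.character(s)))
}

.roll_hash <- function(ints) {
  h <- 17
  for (b in ints) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.file_checksum <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  step <- max(1L, length(bytes) %/% 4096L)
  sprintf("%s-%d", .roll_hash(as.integer(bytes[seq(1L, length(bytes), by = step)])),
          length(bytes))
}
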