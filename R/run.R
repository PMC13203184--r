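## Configuration-driven pipeline entry points -------------------------------

#' Build a validated run configuration
#'
#' One global seed fans out to stage-specific seeds by fixed derivation
#' (hash of the stage name), so stages can be rerun independently.  Unknown
#' fields are rejected.
#'
#' @param phantom a [phantom_config()].
#' @param seed global integer seed.
#' @param test_fraction sequence-level test share.
#' @param validation_fraction frame-level validation share.
#' @param classifier `"hog_svm"` or `"small_cnn"`.
#' @param classifier_config matching configuration object.
#' @param bootstrap a [bootstrap_config()].
#' @param families artifact families to run curves for.
#' @param out_dir results directory.
#' @param learning_curve logical; also run the learning-curve analysis.
#' @param learning_seeds seeds for learning-curve replication.
#' @return Object of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(), seed = 1L,
                       test_fraction = 0.2, validation_fraction = 0.2,
                       classifier = c("hog_svm", "small_cnn"),
                       classifier_config = NULL,
                       bootstrap = bootstrap_config(),
                       families = c("motion_blur", "acoustic_shadow",
                                    "speckle"),
                       out_dir = "results",
                       learning_curve = FALSE,
                       learning_seeds = 1:3) {
  classifier <- match.arg(classifier)
  if (is.null(classifier_config))
    classifier_config <- if (classifier == "hog_svm") hog_config()
                         else cnn_config()
  families <- match.arg(families, several.ok = TRUE)
  structure(list(phantom = phantom, seed = as.integer(seed),
                 test_fraction = test_fraction,
                 validation_fraction = validation_fraction,
                 classifier = classifier,
                 classifier_config = classifier_config,
                 bootstrap = bootstrap, families = families,
                 out_dir = out_dir,
                 learning_curve = isTRUE(learning_curve),
                 learning_seeds = learning_seeds),
            class = "run_config")
}

#' Parse a run configuration from a YAML or JSON file
#'
#' Recognized top-level keys: `seed`, `test_fraction`,
#' `validation_fraction`, `classifier`, `out_dir`, `families`,
#' `learning_curve`, plus nested `phantom` and `bootstrap` sections whose
#' keys are the corresponding constructor arguments.  Unknown keys are an
#' error.
#'
#' @param path file path (`.yaml`/`.yml` needs the yaml package).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "test_fraction", "validation_fraction", "classifier",
             "out_dir", "families", "learning_curve", "learning_seeds",
             "phantom", "bootstrap")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  args <- raw[setdiff(names(raw), c("phantom", "bootstrap"))]
  if (!is.null(raw$phantom)) {
    ph <- raw$phantom
    if (!is.null(ph$sequences_per_class))
      ph$sequences_per_class <- unlist(ph$sequences_per_class)
    if (!is.null(ph$frames_per_class))
      ph$frames_per_class <- unlist(ph$frames_per_class)
    args$phantom <- do.call(phantom_config, ph)
  }
  if (!is.null(raw$bootstrap))
    args$bootstrap <- do.call(bootstrap_config, raw$bootstrap)
  do.call(run_config, args)
}

#' Generate a phantom dataset to disk
#'
#' @param config a [run_config()].
#' @param dir output directory (default `<out_dir>/dataset`).
#' @return The dataset manifest, invisibly.
#' @export
run_generate <- function(config, dir = file.path(config$out_dir, "dataset")) {
  message("generating phantom dataset (seed ", config$seed, ") -> ", dir)
  ds <- generate_dataset(config$phantom, seed = config$seed, dir = dir,
                         keep_frames = FALSE)
  message("wrote ", nrow(ds$manifest), " frames in ",
          length(unique(ds$manifest$sequence_id)), " sequences")
  invisible(ds$manifest)
}

train_configured <- function(config, fit_frames, val_frames, seed) {
  if (config$classifier == "hog_svm")
    train_hog_svm(fit_frames, config = config$classifier_config, seed = seed)
  else
    train_small_cnn(fit_frames, val_frames = val_frames,
                    config = config$classifier_config, seed = seed)
}

#' Run the full robustness experiment
#'
#' Pipeline: generate (in memory) -> sequence-level split -> frame-level
#' validation split -> train -> baseline metrics -> one degradation curve
#' per artifact family -> failure cases at each family's maximum severity
#' -> optional learning curve.  All stage seeds derive from the global
#' seed; rerunning with the same config reproduces every output.
#'
#' @param config a [run_config()].
#' @return List with the trained model, baseline reports, curves, failure
#'   cases and file paths; results are also serialized under
#'   `config$out_dir`.
#' @export
run_experiment <- function(config) {
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  message("stage 1/6: dataset generation")
  ds <- generate_dataset(config$phantom, seed = config$seed)
  manifest <- ds$manifest
  message("stage 2/6: splitting (test fraction ", config$test_fraction, ")")
  split <- split_sequences(manifest, config$test_fraction,
                           seed = derive_seed(config$seed, "split"))
  train_man <- manifest[manifest$sequence_id %in% split$train_sequences, ]
  vsplit <- split_validation_frames(train_man, config$validation_fraction,
                                    seed = derive_seed(config$seed, "val"))
  fit_frames <- ds$frames[vsplit$fit_frames]
  val_frames <- ds$frames[vsplit$validation_frames]
  test_frames <- ds$frames[manifest$frame_id[
    manifest$sequence_id %in% split$test_sequences]]
  message("stage 3/6: training ", config$classifier, " on ",
          length(fit_frames), " frames")
  model <- train_configured(config, fit_frames, val_frames,
                            seed = derive_seed(config$seed, "train"))
  message("stage 4/6: baseline evaluation on ", length(test_frames),
          " test frames")
  baseline_tab <- predict_proba(model, test_frames)
  baseline_frame <- metrics_report(baseline_tab)
  baseline_seq <- metrics_report(aggregate_sequences(baseline_tab))
  curves <- list(); failures <- list()
  for (fam in config$families) {
    message("stage 5/6: degradation curve for ", fam)
    curves[[fam]] <- degradation_curve(
      model, test_frames, fam, boot = config$bootstrap,
      base_seed = derive_seed(config$seed, "artifact", fam))
    smax <- max(curves[[fam]]$severities)
    fc <- failure_cases(baseline_tab,
                        curves[[fam]]$tables[[format(smax)]])
    if (nrow(fc)) {
      fc$artifact <- fam
      fc$severity <- smax
      failures[[fam]] <- fc
    }
  }
  lc <- NULL
  if (config$learning_curve) {
    message("stage 6/6: learning curve")
    lc <- learning_curve(
      ds$frames, manifest, split,
      trainer = function(fr, s) train_configured(config, fr, val_frames, s),
      seeds = config$learning_seeds)
  } else message("stage 6/6: learning curve skipped")

  ## serialize
  model_dir <- file.path(out, "curves", config$classifier)
  if (!dir.exists(model_dir)) dir.create(model_dir, recursive = TRUE)
  for (fam in names(curves))
    utils::write.csv(as.data.frame(curves[[fam]]),
                     file.path(model_dir, paste0(fam, ".csv")),
                     row.names = FALSE)
  fail_df <- if (length(failures)) do.call(rbind, failures)
             else data.frame(sequence_id = character(0),
                             true_view = character(0),
                             baseline_predicted = character(0),
                             baseline_true_prob = numeric(0),
                             degraded_predicted = character(0),
                             degraded_true_prob = numeric(0),
                             delta_true_prob = numeric(0),
                             artifact = character(0),
                             severity = numeric(0))
  utils::write.csv(fail_df, file.path(out, "failures.csv"),
                   row.names = FALSE)
  if (!is.null(lc))
    utils::write.csv(lc, file.path(out, "learning_curve.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(frame = as.data.frame(baseline_frame),
         sequence = as.data.frame(baseline_seq)),
    file.path(out, "metrics_baseline.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = config$seed, classifier = config$classifier,
         test_fraction = config$test_fraction,
         validation_fraction = config$validation_fraction,
         families = config$families,
         bootstrap = unclass(config$bootstrap),
         split_seed = derive_seed(config$seed, "split"),
         train_seed = derive_seed(config$seed, "train")),
    file.path(out, "config.json"), auto_unbox = TRUE)
  invisible(list(model = model, split = split,
                 baseline_frame = baseline_frame, baseline_seq = baseline_seq,
                 curves = curves, failures = fail_df, learning_curve = lc,
                 out_dir = out))
}

#' Render result tables from a completed results directory
#'
#' @param dir a results directory written by [run_experiment()].
#' @return List of data frames (`baseline`, one delta table per family,
#'   `failures`), printed as human-readable text.
#' @export
run_report <- function(dir) {
  needed <- c("metrics_baseline.json", "failures.csv", "config.json")
  missing <- needed[!file.exists(file.path(dir, needed))]
  curve_files <- list.files(file.path(dir, "curves"), recursive = TRUE,
                            pattern = "\\.csv$", full.names = TRUE)
  if (length(missing) || !length(curve_files))
    stop("incomplete results directory; missing: ",
         paste(c(missing, if (!length(curve_files)) "curves/*.csv"),
               collapse = ", "))
  baseline <- jsonlite::read_json(file.path(dir, "metrics_baseline.json"),
                                  simplifyVector = TRUE)
  cat("== Baseline frame-level metrics ==\n")
  print(baseline$frame, row.names = FALSE)
  out <- list(baseline = baseline)
  for (f in curve_files) {
    fam <- sub("\\.csv$", "", basename(f))
    tab <- utils::read.csv(f)
    cat(sprintf("\n== Degradation: %s ==\n", fam))
    print(tab, row.names = FALSE, digits = 3)
    out[[fam]] <- tab
  }
  failures <- utils::read.csv(file.path(dir, "failures.csv"))
  cat(sprintf("\n== Failure cases: %d ==\n", nrow(failures)))
  if (nrow(failures)) print(utils::head(failures, 10), row.names = FALSE)
  out$failures <- failures
  invisible(out)
}
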