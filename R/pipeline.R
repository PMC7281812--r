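#' End-to-end pipeline configuration
#'
#' Bundles every stage of the simulate -> split -> train -> predict ->
#' evaluate pipeline into one object. Every hyperparameter that had to be
#' chosen beyond the reference protocol (restart periods, batch size, loss
#' weight, thresholds, phantom intensities) surfaces here with its default
#' so deviations are visible in one place. All randomness flows from the
#' single `seed` through deterministic sub-seeds (simulation, splitting,
#' initialization and each training stage get their own derived seed).
#'
#' @param n_scans phantoms to simulate.
#' @param phantom a [phantom_config()].
#' @param network a [network_config()].
#' @param loss a [loss_config()].
#' @param stage_in,stage_out zoom-in / zoom-out [stage_config()]s.
#' @param snapshot_epochs zoom-out epochs at which snapshots are captured.
#' @param split_fractions train/dev/test fractions.
#' @param ensemble use the snapshot ensemble (mean of member probability
#'   maps) for test predictions; otherwise the final model.
#' @param finetune run the zoom-out stage; `FALSE` gives the
#'   zoom-in-only ablation variant (reports are labeled accordingly).
#' @param infer_crop inference window; `NULL` for the largest
#'   network-compatible centered window.
#' @param threshold binarization threshold for evaluation.
#' @param n_boot bootstrap iterations for confidence intervals.
#' @param seed global pipeline seed.
#' @return A `run_config` list.
#' @export
run_config <- function(n_scans = 50L,
                       phantom = phantom_config(
                         grid_shape = c(48, 48, 48),
                         lesion_volume_range_mm3 = c(50, 4000)),
                       network = network_config(n_levels = 2L,
                                                base_channels = 4L,
                                                blocks_per_level = 1L,
                                                gn_groups = 2L),
                       loss = loss_config(),
                       stage_in = stage_config(crop_size = c(32, 32, 32),
                                               epochs = 24L,
                                               initial_lr = 1e-3,
                                               restart_period_T0 = 10L),
                       stage_out = stage_config(crop_size = c(48, 48, 48),
                                                epochs = 2L,
                                                initial_lr = 1e-4,
                                                restart_period_T0 = 2L),
                       snapshot_epochs = c(1L, 2L),
                       split_fractions = c(0.76, 0.11, 0.13),
                       ensemble = FALSE, finetune = TRUE,
                       infer_crop = NULL, threshold = 0.5,
                       n_boot = 1000L, seed = 20L) {
  stopifnot(inherits(phantom, "phantom_config"),
            inherits(network, "network_config"),
            inherits(loss, "loss_config"),
            inherits(stage_in, "stage_config"),
            inherits(stage_out, "stage_config"))
  structure(list(n_scans = as.integer(n_scans), phantom = phantom,
                 network = network, loss = loss, stage_in = stage_in,
                 stage_out = stage_out,
                 snapshot_epochs = as.integer(snapshot_epochs),
                 split_fractions = split_fractions, ensemble = ensemble,
                 finetune = finetune, infer_crop = infer_crop,
                 threshold = threshold, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full segmentation pipeline
#'
#' Simulates a phantom cohort, splits it, trains with the zoom-in&out
#' schedule, predicts the test set by center-crop inference (final model or
#' snapshot ensemble) and evaluates. A second run with the same config and
#' seed reproduces the report exactly.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, phantoms (NIfTI),
#'   manifest, training history, per-scan metrics and the summary are
#'   written there.
#' @param verbose print stage progress.
#' @return A `pipeline_run` list: `report` ([evaluate_cohort()] output),
#'   `history`, `network`, `snapshots`, `split`, `variant`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulate: %d phantoms", config$n_scans)
  cohort <- generate_cohort(config$n_scans, config$phantom,
                            seed = derive_seed(seed, 1))
  ids <- vapply(cohort, `[[`, "", "scan_id")

  split <- split_cohort(ids, config$split_fractions,
                        seed = derive_seed(seed, 2))
  train_set <- cohort[ids %in% split$train_ids]
  test_set <- cohort[ids %in% split$test_ids]
  if (length(train_set) == 0 || length(test_set) == 0)
    stop("split produced an empty train or test set")

  say("train: zoom-in %d epochs, zoom-out %d epochs",
      config$stage_in$epochs, if (config$finetune) config$stage_out$epochs
      else 0L)
  net0 <- build_network(config$network, seed = derive_seed(seed, 3))
  stage_in <- config$stage_in
  stage_in$seed <- derive_seed(seed, 4)
  stage_out <- config$stage_out
  stage_out$seed <- derive_seed(seed, 5)
  if (config$finetune) {
    tr <- zoom_in_out(net0, train_set, stage_in, stage_out,
                      snapshot_epochs = config$snapshot_epochs,
                      loss = config$loss, verbose = verbose)
    final <- tr$network
    variant <- "3D-ResU-Net"
  } else {
    tr <- train_stage(net0, train_set, stage_in, loss = config$loss,
                      stage_name = "zoom_in", verbose = verbose)
    final <- tr$network
    tr$snapshots <- list()
    variant <- "3D-ResU-Net-F"
  }

  say("predict: %d test scans (%s)", length(test_set),
      if (config$ensemble && length(tr$snapshots)) "snapshot ensemble"
      else "final model")
  predict_one <- function(sc) {
    if (config$ensemble && length(tr$snapshots))
      ensemble_predict(tr$snapshots, sc$volume, crop_size = config$infer_crop)
    else predict(final, sc$volume, crop_size = config$infer_crop)
  }
  prob_maps <- lapply(test_set, predict_one)
  refs <- lapply(test_set, `[[`, "mask")

  say("evaluate: %d scans", length(refs))
  report <- evaluate_cohort(prob_maps, refs, threshold = config$threshold,
                            n_boot = config$n_boot,
                            seed = derive_seed(seed, 6))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    manifest <- write_cohort_nifti(cohort, file.path(out_dir, "phantoms"))
    write_manifest(manifest, file.path(out_dir, "manifest.csv"), split)
    write.csv(tr$history, file.path(out_dir, "history.csv"),
              row.names = FALSE)
    write.csv(report$scans, file.path(out_dir, "scan_metrics.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(variant = variant, seed = seed,
           summary = summary(report), micro_dsc = report$micro_dsc),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    save_checkpoint(final, file.path(out_dir, "model_final.rds"))
    for (nm in names(tr$snapshots))
      save_checkpoint(tr$snapshots[[nm]],
                      file.path(out_dir, paste0("model_", nm, ".rds")))
  }

  structure(list(report = report, history = tr$history, network = final,
                 network_zoom_in = tr$network_zoom_in,
                 snapshots = tr$snapshots, split = split,
                 variant = variant, config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %s  (seed %d)\n", x$variant, x$config$seed))
  print(x$split)
  print(x$report)
  invisible(x)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML mirrors the [run_config()] structure with one section per
#' sub-configuration.
#'
#' @param path YAML file.
#' @param config a [run_config()].
#' @return `read_run_config` returns a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pick <- function(ctor, fields) do.call(ctor, fields %||% list())
  cfg <- run_config(
    n_scans = y$n_scans %||% 50L,
    phantom = pick(phantom_config, y$phantom),
    network = pick(network_config, y$network),
    loss = pick(loss_config, y$loss),
    stage_in = do.call(stage_config, y$stage_in),
    stage_out = do.call(stage_config, y$stage_out),
    snapshot_epochs = y$snapshot_epochs %||% integer(0),
    split_fractions = unlist(y$split_fractions) %||% c(0.76, 0.11, 0.13),
    ensemble = y$ensemble %||% FALSE,
    finetune = y$finetune %||% TRUE,
    threshold = y$threshold %||% 0.5,
    n_boot = y$n_boot %||% 1000L,
    seed = y$seed %||% 20L)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  y <- list(n_scans = config$n_scans,
            phantom = strip(config$phantom),
            network = unclass(config$network)[c("n_levels", "base_channels",
                                                "channel_growth",
                                                "blocks_per_level",
                                                "gn_groups")],
            loss = strip(config$loss),
            stage_in = strip(config$stage_in),
            stage_out = strip(config$stage_out),
            snapshot_epochs = config$snapshot_epochs,
            split_fractions = config$split_fractions,
            ensemble = config$ensemble, finetune = config$finetune,
            threshold = config$threshold, n_boot = config$n_boot,
            seed = config$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
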