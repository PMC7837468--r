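# end-to-end experiment orchestration:
# simulate -> preprocess -> label -> train (per band) -> sweep -> evaluate
# -> report, all reproducible from one global seed.

#' Precompute band scalograms for a set of segments
#'
#' @param segments list of `mer_segment`.
#' @param band one of `MER_BANDS`.
#' @param params a [morlet_params()].
#' @param image_size output image `c(H, W)`.
#' @param ... passed to [make_band_scalograms()].
#' @return named list of `scalogram`s keyed by segment id.
#' @export
preprocess_cohort <- function(segments, band, params = morlet_params(),
                              image_size = c(64, 64), ...) {
  out <- lapply(segments, make_band_scalograms, band = band, params = params,
                image_size = image_size, ...)
  names(out) <- vapply(segments, function(s) s$segment_id, character(1))
  out
}

#' Assemble a training/test dataset from scalograms and a labeled manifest
#'
#' @param scalograms named list from [preprocess_cohort()].
#' @param manifest a `labeled_manifest` from [attach_labels()].
#' @param split `"train"` or `"test"`.
#' @return list with `x` (H x W x N array), `contra`, `ipsi` (factors),
#'   `patient` (ids), `segment_id`.
#' @export
build_dataset <- function(scalograms, manifest, split = c("train", "test")) {
  split <- match.arg(split)
  rows <- manifest[manifest$split == split, , drop = FALSE]
  if (nrow(rows) == 0) stop_config("no examples in the ", split, " split")
  miss <- setdiff(rows$segment_id, names(scalograms))
  if (length(miss) > 0)
    stop_config("scalograms missing for segments: ",
                paste(utils::head(miss, 5), collapse = ", "))
  imgs <- lapply(rows$segment_id, function(id) scalograms[[id]]$values)
  hw <- dim(imgs[[1]])
  x <- array(unlist(imgs), dim = c(hw[1], hw[2], nrow(rows)))
  list(x = x,
       contra = rows$label_contra,
       ipsi = rows$label_ipsi,
       patient = rows$patient_id,
       segment_id = rows$segment_id)
}

#' Experiment configuration
#'
#' Bundles the cohort, preprocessing, model and evaluation settings of one
#' end-to-end run. The global `seed` deterministically derives the cohort
#' and model seeds, so one knob reproduces the whole experiment.
#'
#' @param cohort a [cohort_config()].
#' @param bands bands to train on (subset of `MER_BANDS`).
#' @param model a [model_config()].
#' @param ratios list of loss-weight pairs for the sweep (`NULL` to skip).
#' @param sweep_band band used for the sweep (default `"50-500"` when
#'   trained, else the first band).
#' @param image_size scalogram image size.
#' @param morlet a [morlet_params()].
#' @param loss_epsilon,min_epoch passed to [select_max_accuracy()].
#' @param save_waveforms write each segment's samples as CSV (off by
#'   default: large).
#' @param seed global integer seed.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              bands = MER_BANDS,
                              model = model_config(),
                              ratios = NULL,
                              sweep_band = NULL,
                              image_size = c(64, 64),
                              morlet = morlet_params(),
                              loss_epsilon = 0.05,
                              min_epoch = 50L,
                              save_waveforms = FALSE,
                              seed = 1L) {
  bands <- vapply(bands, match.arg, character(1), choices = MER_BANDS)
  cohort$seed <- derive_seed(seed, "stage:cohort")
  model$seed <- derive_seed(seed, "stage:model")
  model$input_size <- as.integer(image_size)
  validate_cohort_config(cohort)
  validate_model_config(model)
  structure(list(cohort = cohort, bands = bands, model = model,
                 ratios = ratios,
                 sweep_band = sweep_band %||%
                   (if ("50-500" %in% bands) "50-500" else bands[1]),
                 image_size = as.integer(image_size), morlet = morlet,
                 loss_epsilon = loss_epsilon, min_epoch = as.integer(min_epoch),
                 save_waveforms = isTRUE(save_waveforms),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full experiment
#'
#' Executes every stage in order and writes all artifacts under `out_dir`:
#' `cohort.csv` (patient records), `manifest.csv` (labeled segments),
#' per-band training histories, `band_summary.csv`, `sweep.csv` (when
#' ratios are given), `roc.csv`, `correlations.csv`, a `report.md` summary,
#' and `config.json` (config snapshot, derived seeds, package version) so a
#' run can be reproduced exactly. Waveforms are written as per-segment CSV
#' only when `save_waveforms` is set; scalograms are saved as RDS.
#'
#' @param config an [experiment_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `cohort`, `manifest`, `band_summary`,
#'   `fits`, `sweep`, `roc`, `correlations`, `out_dir`.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  cohort <- stage("simulate", simulate_cohort(config$cohort))
  write_stage_csv(cohort$records, out_dir, "cohort.csv")
  if (config$save_waveforms) {
    wdir <- file.path(out_dir, "waveforms")
    dir.create(wdir, showWarnings = FALSE)
    for (s in cohort$segments)
      utils::write.csv(data.frame(sample = s$samples),
                       file.path(wdir, paste0(s$segment_id, ".csv")),
                       row.names = FALSE)
  }

  manifest <- stage("label", attach_labels(cohort$segments, cohort$records))
  write_stage_csv(manifest, out_dir, "manifest.csv")

  fits <- list(); band_rows <- list(); scal_by_band <- list()
  for (band in config$bands) {
    scal <- stage(paste0("preprocess:", band),
                  preprocess_cohort(cohort$segments, band, config$morlet,
                                    config$image_size))
    scal_by_band[[band]] <- scal
    saveRDS(scal, file.path(out_dir, paste0("scalograms_",
                                            gsub("-", "_", band), ".rds")))
    train <- build_dataset(scal, manifest, "train")
    test <- build_dataset(scal, manifest, "test")
    fit <- stage(paste0("train:", band),
                 fit_classifier(build_model(config$model), train, test))
    fits[[band]] <- fit
    saveRDS(fit$model, file.path(out_dir, paste0("model_",
                                                 gsub("-", "_", band),
                                                 ".rds")))
    write_stage_csv(fit$history, out_dir,
                    paste0("history_", gsub("-", "_", band), ".csv"))
    sel <- select_max_accuracy(fit$history, config$loss_epsilon,
                               config$min_epoch)
    band_rows[[band]] <- data.frame(
      band = band, max_accuracy = sel$accuracy, selected_epoch = sel$epoch,
      stability_last10 = stability(fit$history,
                                   min(10L, nrow(fit$history))))
  }
  band_summary <- do.call(rbind, band_rows)
  rownames(band_summary) <- NULL
  write_stage_csv(band_summary, out_dir, "band_summary.csv")

  sweep <- NULL
  if (!is.null(config$ratios) && length(config$ratios) > 0) {
    scal <- scal_by_band[[config$sweep_band]]
    train <- build_dataset(scal, manifest, "train")
    test <- build_dataset(scal, manifest, "test")
    sweep <- stage("sweep",
                   loss_ratio_sweep(train, test, config$ratios, config$model,
                                    config$loss_epsilon, config$min_epoch))
    write_stage_csv(sweep, out_dir, "sweep.csv")
  }

  # ROC from the best band's final-epoch model, contralateral head
  best_band <- band_summary$band[which.max(band_summary$max_accuracy)]
  test <- build_dataset(scal_by_band[[best_band]], manifest, "test")
  probs <- predict_classifier(fits[[best_band]]$model, test$x)
  roc <- stage("evaluate",
               roc_auc(probs$contra[, "good"], test$contra))
  write_stage_csv(data.frame(threshold = roc$thresholds, tpr = roc$tpr,
                             fpr = roc$fpr), out_dir, "roc.csv")

  correlations <- correlation_report(cohort$records)
  write_stage_csv(correlations, out_dir, "correlations.csv")

  report <- c(
    "# MER-DBS outcome prediction report", "",
    sprintf("- patients: %d; segments: %d", nrow(cohort$records),
            length(cohort$segments)),
    sprintf("- global seed: %d", config$seed), "",
    "## Band comparison (contralateral max accuracy)", "",
    sprintf("- %s: accuracy %.4f at epoch %d (stability %.4f)",
            band_summary$band, band_summary$max_accuracy,
            band_summary$selected_epoch, band_summary$stability_last10),
    "",
    sprintf("## ROC (band %s, contralateral head)", best_band), "",
    sprintf("- AUC: %.4f", roc$auc), "")
  if (!is.null(sweep))
    report <- c(report, "## Loss-ratio sweep", "",
                sprintf("- %g:%g -> max accuracy %.4f at epoch %d",
                        sweep$w_contra, sweep$w_ipsi, sweep$max_accuracy,
                        sweep$selected_epoch), "")
  report <- c(report, "## Cohort correlations", "",
              sprintf("- %s: r = %.3f (p = %.3g, n = %d)",
                      correlations$quantity, correlations$r,
                      correlations$p, correlations$n))
  writeLines(report, file.path(out_dir, "report.md"))

  snapshot <- list(
    config = config[setdiff(names(config), "morlet")],
    morlet = unclass(config$morlet),
    derived_seeds = list(cohort = config$cohort$seed,
                         model = config$model$seed),
    package_version = as.character(utils::packageVersion("merdbs")))
  jsonlite::write_json(snapshot, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)

  invisible(list(cohort = cohort, manifest = manifest,
                 band_summary = band_summary, fits = fits, sweep = sweep,
                 roc = roc, correlations = correlations, out_dir = out_dir))
}
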