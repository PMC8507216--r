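## One-call end-to-end pipeline driver: simulate -> preprocess/extract ->
## select -> fit -> evaluate, writing every intermediate artifact and a
## run manifest whose digests are reproducible for identical
## configurations.

#' @noRd
stage_log <- function(verbose, stage, t0) {
  if (verbose)
    message(sprintf("[radonset] %-10s %.1fs", stage,
                    (proc.time() - t0)[3]))
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates the cohort and the development/validation split, extracts the
#' full radiomics feature table from per-subject phantoms, fits the
#' rad-score and combined models on the development split
#' ([radonset()]), and evaluates both splits ([evaluate_model()]). All
#' tables and reports are written under `out_dir` (cohort and features as
#' CSV, model and evaluation summaries as JSON, optionally the phantom
#' NIfTI pairs) together with a `manifest.json` recording the
#' configuration hash, package version, seeds and per-artifact md5
#' digests; identical configurations reproduce identical digests.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Log per-stage timing to stderr.
#' @return A list of class `radonset_run`: `manifest`, `cohort`,
#'   `features`, `fit`, `eval_development`, `eval_validation`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile(),
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  t0 <- proc.time()
  cohort <- generate_cohort(config$cohort)
  cohort <- split_cohort(cohort, n_dev = config$n_dev, n_val = config$n_val,
                         stratify = TRUE, seed = config$seed)
  stage_log(verbose, "simulate", t0)

  t0 <- proc.time()
  volumes <- NULL
  if (config$save_volumes) {
    vol_dir <- file.path(out_dir, "volumes")
    dir.create(vol_dir, showWarnings = FALSE)
  }
  features <- extract_cohort(cohort, pspec = config$phantom,
                             config = config$extract)
  if (config$save_volumes) {
    for (i in seq_len(nrow(cohort))) {
      pair <- generate_phantom(cohort[i, ], config$phantom,
                               seed = config$phantom$seed + i)
      write_image_pair(pair,
                       file.path(vol_dir, paste0(cohort$id[i], "_image.nii.gz")),
                       file.path(vol_dir, paste0(cohort$id[i], "_mask.nii.gz")))
    }
  }
  stage_log(verbose, "extract", t0)

  t0 <- proc.time()
  fit <- radonset(features, cohort, alpha = config$alpha,
                  rho_max = config$rho_max, n_folds = config$n_folds,
                  seed = config$seed)
  stage_log(verbose, "fit", t0)

  t0 <- proc.time()
  ev_dev <- evaluate_model(fit, features, cohort, split = "development")
  ev_val <- evaluate_model(fit, features, cohort, split = "validation")
  stage_log(verbose, "evaluate", t0)

  cohort_path <- file.path(out_dir, "cohort.csv")
  features_path <- file.path(out_dir, "features.csv")
  write_cohort_csv(cohort, cohort_path)
  write_table_17g(features, features_path)
  save_config(config, file.path(out_dir, "config.json"))

  model_json <- list(
    radscore = list(intercept = fit$radscore_model$intercept,
                    coefficients = as.list(fit$radscore_model$coefficients),
                    source = fit$radscore_model$source,
                    standardization = list(
                      mean = as.list(fit$radscore_model$standardization$mean[
                        names(fit$radscore_model$coefficients)]),
                      sd = as.list(fit$radscore_model$standardization$sd[
                        names(fit$radscore_model$coefficients)]))),
    combined = list(coefficients = as.list(fit$combined_model$coefficients),
                    separation = fit$combined_model$separation),
    clinical_variables = fit$clinical_variables,
    seed = fit$seed)
  jsonlite::write_json(model_json, file.path(out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report_json <- lapply(list(development = ev_dev, validation = ev_val),
                        function(ev) list(
    n = ev$n,
    auc_radiomics = ev$roc_radiomics$auc,
    ci_radiomics = ev$roc_radiomics$ci,
    auc_combined = ev$roc_combined$auc,
    ci_combined = ev$roc_combined$ci,
    sens_radiomics = ev$youden_radiomics$sensitivity,
    spec_radiomics = ev$youden_radiomics$specificity,
    sens_combined = ev$youden_combined$sensitivity,
    spec_combined = ev$youden_combined$specificity,
    delong_p = ev$delong$p, mcnemar_p = ev$mcnemar$p,
    hl_p_combined = ev$hosmer_lemeshow_combined$p %||% NA,
    dca_range_radiomics = ev$dca_radiomics$range,
    dca_range_combined = ev$dca_combined$range))
  jsonlite::write_json(report_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  artifacts <- c("cohort.csv", "features.csv", "config.json", "model.json",
                 "report.json")
  digests <- vapply(artifacts, function(f)
    unname(tools::md5sum(file.path(out_dir, f))), character(1))
  manifest <- list(config_digest = object_digest(unclass(config)),
                   package_version = as.character(utils::packageVersion("radonset")),
                   seed = config$seed,
                   artifact_digests = as.list(digests),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  structure(list(manifest = manifest, out_dir = out_dir, cohort = cohort,
                 features = features, fit = fit,
                 eval_development = ev_dev, eval_validation = ev_val),
            class = "radonset_run")
}

#' @export
print.radonset_run <- function(x, ...) {
  cat("radonset pipeline run\n")
  cat("  output:", x$out_dir, "\n")
  cat(sprintf("  cohort: %d subjects (%d dev / %d val)\n", nrow(x$cohort),
              sum(x$cohort$split == "development"),
              sum(x$cohort$split == "validation")))
  print(x$eval_validation)
  invisible(x)
}
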