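## File I/O: NIfTI volume/mask pairs, cohort CSV tables, and JSON
## configuration blocks. CSV is the interchange format for tables and JSON
## for models/configs/reports; floats are serialized with 17 significant
## digits so that manifests are bit-stable across runs.

#' Read a NIfTI image/mask pair
#'
#' Voxel spacing is taken from the NIfTI header; the mask is binarized at
#' `> 0`. Shape mismatches and non-finite voxels are errors.
#'
#' @param image_path,mask_path Paths to NIfTI files (`.nii` / `.nii.gz`).
#' @return A list with `volume` ([ct_volume]) and `mask` ([voi_mask]).
#' @export
read_image_pair <- function(image_path, mask_path) {
  for (p in c(image_path, mask_path))
    if (!file.exists(p)) stop_radonset("file not found: ", p)
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  if (!identical(dim(img), dim(msk)))
    stop_radonset("image and mask shapes differ")
  sp <- RNifti::pixdim(img)[1:3]
  vol <- ct_volume(array(as.numeric(img), dim = dim(img)), sp)
  list(volume = vol, mask = voi_mask(array(msk > 0, dim = dim(msk)), sp))
}

#' Write a phantom (image and mask) as NIfTI
#'
#' @param pair A list with `volume` and `mask` (see [generate_phantom()]).
#' @param image_path,mask_path Output paths (`.nii.gz`).
#' @return Invisibly, the two paths.
#' @export
write_image_pair <- function(pair, image_path, mask_path) {
  img <- RNifti::asNifti(pair$volume$voxels, pixdim = pair$volume$spacing)
  msk <- RNifti::asNifti(array(as.integer(pair$mask$voxels),
                               dim = dim(pair$mask$voxels)),
                         pixdim = pair$mask$spacing)
  RNifti::writeNifti(img, image_path)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(image_path, mask_path))
}

.cohort_required <- c("id", "tfs_class", "age", "sex", "nihss", "aspects",
                      "hypertension", "diabetes", "hyperlipidemia",
                      "atrial_fibrillation", "smoking", "alcohol", "hvs",
                      "ica_occlusion", "collateral_grade", "side")

#' Read a cohort table from CSV
#'
#' The TFS label is parsed from a `tfs_class` column (`early`/`late`) or,
#' if absent, from a `tfs_hours` column (hours <= 4.5 map to `early`).
#' Range invariants (ASPECTS 0-10, NIHSS 0-42, collateral grade 0-3) are
#' enforced with the offending row reported. Unknown columns are kept.
#'
#' @param path CSV file path.
#' @return A validated cohort data.frame (with a `split` column, defaulted
#'   to `"unassigned"` when absent).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_radonset("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(df$tfs_class)) {
    if (is.null(df$tfs_hours))
      stop_radonset("cohort CSV needs a 'tfs_class' or 'tfs_hours' column")
    bad <- which(!is.finite(df$tfs_hours) | df$tfs_hours < 0)
    if (length(bad))
      stop_radonset("unparseable 'tfs_hours' at row(s) ",
                    paste(head(bad, 5), collapse = ", "))
    df$tfs_class <- ifelse(df$tfs_hours <= 4.5, "early", "late")
  }
  miss <- setdiff(.cohort_required, names(df))
  if (length(miss))
    stop_radonset("cohort CSV missing column(s): ", paste(miss, collapse = ", "))
  for (b in c("hypertension", "diabetes", "hyperlipidemia",
              "atrial_fibrillation", "smoking", "alcohol", "hvs",
              "ica_occlusion"))
    df[[b]] <- as.logical(df[[b]])
  if (is.null(df$split)) df$split <- "unassigned"
  validate_cohort(df)
  df
}

## 17-significant-digit CSV writer for reproducible manifests.
#' @noRd
write_table_17g <- function(df, path) {
  out <- df
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort table to CSV
#'
#' @param cohort Cohort data.frame.
#' @param path Output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  write_table_17g(cohort, path)
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters. The object round-trips through JSON
#' ([save_config()] / [load_config()]) without loss, and every stochastic
#' stage's seed is part of it.
#'
#' @param cohort A [cohort_spec()].
#' @param phantom A [phantom_spec()].
#' @param extract An [extract_config()].
#' @param n_dev,n_val Development/validation split sizes.
#' @param alpha,rho_max,n_folds Selection parameters (see [radonset()]).
#' @param dca_grid_step Decision-curve threshold grid step.
#' @param seed Master seed for split/folds.
#' @param save_volumes Write phantom NIfTI pairs during [run_pipeline()]
#'   (default TRUE; disable for speed when only tables are needed).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), phantom = phantom_spec(),
                            extract = extract_config(),
                            n_dev = 85L, n_val = 38L,
                            alpha = 0.05, rho_max = 0.9, n_folds = 10L,
                            dca_grid_step = 0.01,
                            seed = .radonset_default_seed,
                            save_volumes = TRUE) {
  check_flag(save_volumes, "save_volumes")
  structure(list(cohort = cohort, phantom = phantom, extract = extract,
                 n_dev = as.integer(n_dev), n_val = as.integer(n_val),
                 alpha = alpha, rho_max = rho_max,
                 n_folds = as.integer(n_folds),
                 dca_grid_step = dca_grid_step, seed = as.integer(seed),
                 save_volumes = save_volumes),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  plain <- strip(config)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config(
    cohort = do.call(cohort_spec, raw$cohort[setdiff(names(raw$cohort), NULL)]),
    phantom = do.call(phantom_spec, raw$phantom),
    extract = extract_config(
      preprocess = do.call(preprocess_config, raw$extract$preprocess),
      angles = raw$extract$angles, offsets = raw$extract$offsets),
    n_dev = raw$n_dev, n_val = raw$n_val, alpha = raw$alpha,
    rho_max = raw$rho_max, n_folds = raw$n_folds,
    dca_grid_step = raw$dca_grid_step, seed = raw$seed,
    save_volumes = raw$save_volumes)
  cfg
}
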