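## Assembly of the full radiomics feature vector. The default grid yields
## exactly 396 named features:
##   histogram 42 + formfactor 9 + haralick 10
##   + GLCM  8 bases x (4 angles x 3 offsets + 2 aggregations x 3 offsets) = 144
##   + RLM  10 bases x (4 angles x 3 steps   + 2 aggregations x 3 steps)  = 180
##   + GLSZM 11
## Texture names follow the Base_angleA_offsetK[_SD] token grid, e.g.
## "LongRunEmphasis_angle135_offset4" or "Inertia_AllDirection_offset7_SD".

.glcm_bases <- c("Energy", "Entropy", "Inertia", "Correlation",
                 "InverseDifferenceMoment", "ClusterShade",
                 "ClusterProminence", "HaralickCorrelation")
.rlm_bases <- c("ShortRunEmphasis", "LongRunEmphasis", "GreyLevelNonuniformity",
                "RunLengthNonuniformity", "LowGreyLevelRunEmphasis",
                "HighGreyLevelRunEmphasis", "ShortRunLowGreyLevelEmphasis",
                "ShortRunHighGreyLevelEmphasis", "LongRunLowGreyLevelEmphasis",
                "LongRunHighGreyLevelEmphasis")

#' Feature-extraction configuration
#'
#' @param preprocess A [preprocess_config()].
#' @param angles In-plane texture angles in degrees.
#' @param offsets Displacements (GLCM) / ray sampling steps (RLM).
#' @return A list of class `extract_config`.
#' @export
extract_config <- function(preprocess = preprocess_config(),
                           angles = c(0, 45, 90, 135),
                           offsets = c(1L, 4L, 7L)) {
  stopifnot(inherits(preprocess, "preprocess_config"))
  if (!all(angles %in% c(0, 45, 90, 135)))
    stop_radonset("angles must be a subset of {0, 45, 90, 135}")
  if (any(offsets < 1)) stop_radonset("offsets must be >= 1")
  structure(list(preprocess = preprocess, angles = as.numeric(angles),
                 offsets = as.integer(offsets)),
            class = "extract_config")
}

#' @noRd
texture_block_names <- function(bases, angles, offsets) {
  unlist(lapply(offsets, function(k) c(
    unlist(lapply(angles, function(a)
      sprintf("%s_angle%g_offset%d", bases, a, k))),
    sprintf("%s_AllDirection_offset%d", bases, k),
    sprintf("%s_AllDirection_offset%d_SD", bases, k))))
}

#' Names of the default feature grid
#'
#' @param config An [extract_config()].
#' @return Character vector of the full feature-name inventory (396 names
#'   under the default configuration), in deterministic extraction order.
#' @export
feature_names_default <- function(config = extract_config()) {
  hist_names <- c("Min", "Max", "Range", "Mean", "Median", "Mode",
                  "StandardDeviation", "Variance", "MeanAbsoluteDeviation",
                  "RootMeanSquare", "Energy", "Entropy", "Uniformity",
                  "Skewness", "Kurtosis", "CoefficientOfVariation",
                  "InterquartileRange", "RobustMeanAbsoluteDeviation",
                  "Percentile10to90Mean", "TotalExcessOverMedian",
                  "VoxelCount", paste0("Percentile", c(1, seq(5, 95, 5), 99)))
  ## the mask voxel count is renamed on the grid: "VoxelCount" is taken by
  ## the histogram family
  shape_names <- c("Volume", "MaskVoxelCount", "SurfaceArea",
                   "SurfaceToVolumeRatio", "Compactness1", "Compactness2",
                   "Sphericity", "SphericalDisproportion", "Maximum3DDiameter")
  haralick_names <- c("AngularSecondMoment", "Contrast", "Correlation",
                      "SumOfSquaresVariance", "InverseDifferenceMoment",
                      "SumAverage", "SumEntropy", "SumVariance",
                      "DifferenceEntropy", "DifferenceVariance")
  glszm_names <- c("SmallZoneEmphasis", "LargeZoneEmphasis",
                   "GreyLevelNonuniformity", "ZoneSizeNonuniformity",
                   "ZonePercentage", "LowGreyLevelZoneEmphasis",
                   "HighGreyLevelZoneEmphasis", "SmallZoneLowGreyLevelEmphasis",
                   "SmallZoneHighGreyLevelEmphasis",
                   "LargeZoneLowGreyLevelEmphasis",
                   "LargeZoneHighGreyLevelEmphasis")
  c(hist_names, shape_names, haralick_names,
    texture_block_names(.glcm_bases, config$angles, config$offsets),
    texture_block_names(.rlm_bases, config$angles, config$offsets),
    glszm_names)
}

#' @noRd
texture_block_values <- function(per_angle_fun, bases, angles, offsets) {
  vals <- lapply(offsets, function(k) {
    pa <- lapply(angles, function(a) {
      v <- tryCatch(per_angle_fun(a, k), error = function(e)
        setNames(rep(NA_real_, length(bases)), bases))
      v[bases]
    })
    mat <- do.call(rbind, pa)  # angles x bases
    agg <- apply(mat, 2, function(col) aggregate_directions(col))
    c(as.vector(t(mat)), agg["mean", ], agg["SD", ])
  })
  unlist(vals)
}

#' Extract the full radiomics feature vector for one subject
#'
#' Runs preprocessing ([preprocess_volume()]) and then all six feature
#' families over the configured grid. The result is a deterministic named
#' vector; the default configuration yields exactly 396 features, including
#' the six signature features
#' `LongRunEmphasis_angle135_offset4`, `SurfaceArea`,
#' `Inertia_AllDirection_offset7_SD`, `ClusterShade_AllDirection_offset1_SD`,
#' `Percentile20` and `LongRunLowGreyLevelEmphasis_angle90_offset7`.
#'
#' @param volume A [ct_volume].
#' @param mask A [voi_mask] aligned with `volume`.
#' @param config An [extract_config()].
#' @return Named numeric vector over [feature_names_default()].
#' @export
extract_features <- function(volume, mask, config = extract_config()) {
  stopifnot(inherits(config, "extract_config"))
  pp <- preprocess_volume(volume, mask, config$preprocess)
  disc <- pp$disc
  nb <- config$preprocess$n_bins

  hist_vals <- histogram_features(pp$volume, pp$mask, n_bins = nb,
                                  breaks = seq(0, 1, length.out = nb + 1))
  shape_vals <- shape_features(pp$mask)
  har_vals <- haralick_features(disc)
  glcm_vals <- texture_block_values(
    function(a, k) glcm_features(cooccurrence_matrix(disc, a, k)),
    .glcm_bases, config$angles, config$offsets)
  rlm_vals <- texture_block_values(
    function(a, k) rlm_features(run_length_matrix(disc, a, k)),
    .rlm_bases, config$angles, config$offsets)
  glszm_vals <- glszm_features(size_zone_matrix(disc))

  out <- c(hist_vals, shape_vals, har_vals, glcm_vals, rlm_vals, glszm_vals)
  out <- unname(out)
  names(out) <- feature_names_default(config)
  out
}

#' Extract features for every subject of a cohort
#'
#' Generates (or accepts) one phantom per subject and extracts the full
#' feature vector, returning a feature table with one row per subject.
#'
#' @param cohort A cohort data.frame (see [generate_cohort()]).
#' @param pspec A [phantom_spec()] used when `volumes` is `NULL`.
#' @param config An [extract_config()].
#' @param volumes Optional named list (by subject id) of
#'   `list(volume =, mask =)` pairs; when given, phantoms are not generated.
#' @param seed Base seed for phantom generation (per-subject seeds are
#'   derived as `seed + row index`).
#' @return A data.frame with `id` plus one column per feature.
#' @export
extract_cohort <- function(cohort, pspec = phantom_spec(),
                           config = extract_config(), volumes = NULL,
                           seed = NULL) {
  validate_cohort(cohort)
  seed <- seed %||% pspec$seed
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    pair <- if (!is.null(volumes)) volumes[[cohort$id[i]]]
            else generate_phantom(cohort[i, ], pspec, seed = seed + i)
    extract_features(pair$volume, pair$mask, config)
  })
  ft <- as.data.frame(do.call(rbind, rows))
  cbind(id = cohort$id, ft, stringsAsFactors = FALSE)
}
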