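## Preprocessing: isotropic resampling, intensity windowing/normalization,
## and gray-level discretization. All texture features are computed on the
## discretized representation produced here, so these defaults (1 mm
## isotropic grid, brain window [0, 80] HU, 64 fixed bins on [0, 1])
## define the gray-level scale shared by every subject.

#' Preprocessing configuration
#'
#' @param window HU window `c(low, high)` used for intensity normalization
#'   (default the brain window `c(0, 80)`).
#' @param n_bins Number of gray levels for discretization (default 64).
#' @param target_spacing_mm Isotropic resampling target in mm (default 1).
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(window = c(0, 80), n_bins = 64L,
                              target_spacing_mm = 1) {
  if (length(window) != 2L || window[1] >= window[2])
    stop_radonset("'window' must be c(low, high) with low < high")
  if (n_bins < 2L) stop_radonset("'n_bins' must be at least 2")
  check_number(target_spacing_mm, "target_spacing_mm", lower = 1e-6)
  structure(list(window = as.numeric(window), n_bins = as.integer(n_bins),
                 target_spacing_mm = as.numeric(target_spacing_mm)),
            class = "preprocess_config")
}

## Trilinear sampling of a 3D array at fractional voxel coordinates
## (1-based, clamped to the grid).
#' @noRd
trilinear_sample <- function(a, x, y, z) {
  d <- dim(a)
  x <- pmin(pmax(x, 1), d[1]); y <- pmin(pmax(y, 1), d[2]); z <- pmin(pmax(z, 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(x))
  if (d[2] == 1L) y0 <- rep(1, length(y))
  if (d[3] == 1L) z0 <- rep(1, length(z))
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  at <- function(i, j, k) a[cbind(i, j, k)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x1, y0, z0)) +
              fy * ((1 - fx) * at(x0, y1, z0) + fx * at(x1, y1, z0))) +
  fz * ((1 - fy) * ((1 - fx) * at(x0, y0, z1) + fx * at(x1, y0, z1)) +
        fy * ((1 - fx) * at(x0, y1, z1) + fx * at(x1, y1, z1)))
}

#' Resample a volume and its mask to an isotropic grid
#'
#' Intensities are trilinear-interpolated; the mask is resampled nearest
#' neighbour and stays binary. The output extent along each axis is
#' `round(extent_mm / target_spacing)` voxels. An input already isotropic at
#' the target is returned unchanged.
#'
#' @param volume A [ct_volume].
#' @param mask A [voi_mask] aligned with `volume`.
#' @param target_spacing Target isotropic spacing in mm.
#' @return A list with resampled `volume` and `mask`.
#' @export
resample_isotropic <- function(volume, mask, target_spacing = 1) {
  check_aligned(volume, mask)
  check_number(target_spacing, "target_spacing", lower = 1e-6)
  sp <- volume$spacing
  if (max(abs(sp - target_spacing)) < 1e-9)
    return(list(volume = volume, mask = mask))
  d <- dim(volume$voxels)
  newd <- pmax(1L, as.integer(round(d * sp / target_spacing)))
  ## voxel-centre coordinates: centre i sits at (i - 0.5) * spacing
  cx <- ((seq_len(newd[1]) - 0.5) * target_spacing) / sp[1] + 0.5
  cy <- ((seq_len(newd[2]) - 0.5) * target_spacing) / sp[2] + 0.5
  cz <- ((seq_len(newd[3]) - 0.5) * target_spacing) / sp[3] + 0.5
  g <- expand.grid(x = cx, y = cy, z = cz)
  newvox <- array(trilinear_sample(volume$voxels, g$x, g$y, g$z), dim = newd)
  dm <- dim(mask$voxels)
  rx <- pmin(pmax(round(g$x), 1), dm[1])
  ry <- pmin(pmax(round(g$y), 1), dm[2])
  rz <- pmin(pmax(round(g$z), 1), dm[3])
  newmask <- array(mask$voxels[cbind(rx, ry, rz)], dim = newd)
  if (!any(newmask)) stop_radonset("resampling emptied the mask")
  list(volume = ct_volume(newvox, rep(target_spacing, 3)),
       mask = voi_mask(newmask, rep(target_spacing, 3)))
}

#' Window and normalize in-mask intensities
#'
#' In-mask HU values are clipped to `window` and affinely mapped to
#' `[0, 1]`; voxels outside the mask are left untouched.
#'
#' @param volume A [ct_volume].
#' @param mask A [voi_mask] aligned with `volume`.
#' @param window HU window `c(low, high)`.
#' @return A [ct_volume] with normalized in-mask values.
#' @export
normalize_intensity <- function(volume, mask, window = c(0, 80)) {
  check_aligned(volume, mask)
  if (length(window) != 2L || window[1] >= window[2])
    stop_radonset("'window' must be c(low, high) with low < high")
  v <- volume$voxels
  inm <- mask$voxels
  v[inm] <- (pmin(pmax(v[inm], window[1]), window[2]) - window[1]) /
    (window[2] - window[1])
  ct_volume(v, volume$spacing)
}

#' Discretize normalized in-mask intensities to gray levels
#'
#' Levels are `min(n_bins, floor(value * n_bins) + 1)` with uniform bin
#' edges on `[0, 1]` (values on an internal edge go to the higher bin);
#' out-of-mask voxels get level 0.
#'
#' @param volume A [ct_volume] with in-mask values in `[0, 1]` (see
#'   [normalize_intensity()]).
#' @param mask A [voi_mask] aligned with `volume`.
#' @param n_bins Number of gray levels (>= 2).
#' @return A list of class `discretized_voi` with `levels` (integer array,
#'   0 outside the mask), `n_bins`, `spacing`, and `mask`.
#' @export
discretize_gray_levels <- function(volume, mask, n_bins = 64L) {
  check_aligned(volume, mask)
  if (n_bins < 2L) stop_radonset("'n_bins' must be at least 2")
  v <- volume$voxels[mask$voxels]
  if (any(v < -1e-9 | v > 1 + 1e-9))
    stop_radonset("in-mask values must lie in [0, 1]; run normalize_intensity first")
  lev <- array(0L, dim(volume$voxels))
  lev[mask$voxels] <- pmin(as.integer(n_bins),
                           as.integer(floor(pmin(pmax(v, 0), 1) * n_bins)) + 1L)
  structure(list(levels = lev, n_bins = as.integer(n_bins),
                 spacing = volume$spacing, mask = mask$voxels),
            class = "discretized_voi")
}

#' Run the full preprocessing chain
#'
#' Resamples to the isotropic target, windows/normalizes, and discretizes.
#'
#' @param volume A [ct_volume].
#' @param mask A [voi_mask] aligned with `volume`.
#' @param config A [preprocess_config()].
#' @return A list with `volume` (normalized, resampled), `mask` (resampled),
#'   and `disc` (the [discretize_gray_levels()] output).
#' @export
preprocess_volume <- function(volume, mask, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  rs <- resample_isotropic(volume, mask, config$target_spacing_mm)
  nv <- normalize_intensity(rs$volume, rs$mask, config$window)
  disc <- discretize_gray_levels(nv, rs$mask, config$n_bins)
  list(volume = nv, mask = rs$mask, disc = disc)
}
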