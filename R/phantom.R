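## CT-like phantom volumes with a volume-of-interest (VOI) mask.
##
## Phantoms are a synthetic stand-in for patient non-contrast CT: a textured
## background at brain-parenchyma attenuation, a hemispheric VOI template
## (the "MCA territory"), and an ellipsoidal hypodense lesion whose density
## decrement and textural heterogeneity depend on the TFS class (late
## lesions are more hypodense and more heterogeneous) and whose extent
## grows as ASPECTS falls.

#' Construct a CT volume
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing Positive length-3 voxel spacing in mm.
#' @return Object of class `ct_volume` (list with `voxels`, `spacing`).
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_radonset("'voxels' must be a 3D array")
  if (any(!is.finite(voxels))) stop_radonset("voxel values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_radonset("'spacing' must be three positive mm values")
  structure(list(voxels = voxels, spacing = spacing), class = "ct_volume")
}

#' Construct a VOI mask
#'
#' @param voxels 3D logical (or 0/1) array; must contain at least one voxel.
#' @param spacing Positive length-3 voxel spacing in mm.
#' @return Object of class `voi_mask`.
#' @export
voi_mask <- function(voxels, spacing = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_radonset("'voxels' must be a 3D array")
  m <- array(voxels > 0, dim = dim(voxels))
  if (!any(m)) stop_radonset("mask is empty")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_radonset("'spacing' must be three positive mm values")
  structure(list(voxels = m, spacing = spacing), class = "voi_mask")
}

#' @noRd
check_aligned <- function(volume, mask) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "voi_mask"))
  if (!identical(dim(volume$voxels), dim(mask$voxels)))
    stop_radonset("volume and mask shapes differ")
  if (max(abs(volume$spacing - mask$spacing)) > 1e-9)
    stop_radonset("volume and mask spacings differ")
  invisible(TRUE)
}

#' Specification of the phantom generator
#'
#' @param shape Volume shape in voxels (default 48^3).
#' @param spacing Voxel spacing in mm (default 1 mm isotropic).
#' @param bg_mean,bg_sd Background tissue HU mean and texture SD.
#' @param bg_corr Background texture correlation length (voxels).
#' @param decrement Lesion HU decrement per class, `c(early, late)`; the
#'   early magnitude must not exceed the late one (late infarcts are more
#'   hypodense).
#' @param het_sd Extra lesion texture SD per class, `c(early, late)`.
#' @param het_corr Lesion texture correlation length per class (voxels).
#' @param extent_base,extent_slope Lesion extent rule: the lesion occupies
#'   `extent_base + extent_slope * (10 - aspects) / 10` of the VOI volume
#'   (lower ASPECTS, larger lesion); the fraction must stay in (0, 1].
#' @param voi_radius_frac VOI hemisphere radius as a fraction of the
#'   smallest volume extent.
#' @param seed Integer master seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L), spacing = c(1, 1, 1),
                         bg_mean = 35, bg_sd = 3, bg_corr = 1.5,
                         decrement = c(early = 1.5, late = 3),
                         het_sd = c(early = 1.5, late = 2.5),
                         het_corr = c(early = 1.2, late = 2),
                         extent_base = 0.05, extent_slope = 0.6,
                         voi_radius_frac = 0.42,
                         seed = .radonset_default_seed) {
  if (any(spacing <= 0)) stop_radonset("spacing must be positive")
  if (abs(decrement[1]) > abs(decrement[2]))
    stop_radonset("early decrement magnitude must not exceed the late one")
  if (extent_base <= 0 || extent_base + extent_slope > 1 + 1e-9)
    stop_radonset("lesion extent fraction must lie in (0, 1]")
  cls2 <- c("early", "late")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 bg_mean = as.numeric(bg_mean), bg_sd = as.numeric(bg_sd),
                 bg_corr = as.numeric(bg_corr),
                 decrement = setNames(as.numeric(decrement), cls2),
                 het_sd = setNames(as.numeric(het_sd), cls2),
                 het_corr = setNames(as.numeric(het_corr), cls2),
                 extent_base = as.numeric(extent_base),
                 extent_slope = as.numeric(extent_slope),
                 voi_radius_frac = as.numeric(voi_radius_frac),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## Separable Gaussian smoothing of a 3D array (replicate-padded edges).
#' @noRd
gaussian_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  h <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-h:h) / sigma)^2)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, nrow = d[1])
    mp <- rbind(m[rep(1L, h), , drop = FALSE], m,
                m[rep(nrow(m), h), , drop = FALSE])
    f <- stats::filter(mp, k, sides = 2)
    f <- f[(h + 1L):(h + d[1]), , drop = FALSE]
    aperm(array(f, d), order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  a
}

## Correlated Gaussian field with unit variance (empirically rescaled).
#' @noRd
correlated_field <- function(shape, corr_len) {
  f <- gaussian_smooth3(array(rnorm(prod(shape)), dim = shape), corr_len)
  s <- sd(f)
  if (s < .Machine$double.eps) f else f / s
}

## Hemispheric VOI template: half-ball scaled to the volume.
#' @noRd
voi_template <- function(shape, radius_frac) {
  ctr <- (shape + 1) / 2
  r <- radius_frac * min(shape)
  x <- slice.index(array(0, shape), 1)
  y <- slice.index(array(0, shape), 2)
  z <- slice.index(array(0, shape), 3)
  d2 <- (x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2
  (d2 <= r^2) & (x >= ctr[1])
}

#' Generate a CT-like phantom for one subject
#'
#' Builds the textured background, the hemispheric VOI, and a hypodense
#' lesion with class-dependent decrement and heterogeneity. The lesion is
#' the `extent`-fraction ellipsoidal core of the VOI, where `extent`
#' follows the ASPECTS rule in [phantom_spec()]. Identical
#' `(record, pspec, seed)` reproduce identical voxels.
#'
#' @param record A single-row cohort data.frame (needs `tfs_class`,
#'   `aspects`, and optionally `id` used for per-subject seed derivation).
#' @param pspec A [phantom_spec()].
#' @param seed Optional integer seed; default derives one from `pspec$seed`
#'   and the numeric part of `record$id`.
#' @return A list with elements `volume` ([ct_volume]), `mask`
#'   ([voi_mask]) and `lesion` (logical array marking the lesion core,
#'   useful for effect-direction checks).
#' @examples
#' cohort <- generate_cohort(cohort_spec())
#' ph <- generate_phantom(cohort[1, ], phantom_spec(shape = c(24, 24, 24)))
#' mean(ph$volume$voxels[ph$mask$voxels])
#' @export
generate_phantom <- function(record, pspec = phantom_spec(), seed = NULL) {
  stopifnot(inherits(pspec, "phantom_spec"))
  if (is.null(record$tfs_class) || is.null(record$aspects))
    stop_radonset("record must carry 'tfs_class' and 'aspects'")
  cls <- as.character(record$tfs_class[1])
  if (!cls %in% c("early", "late")) stop_radonset("unknown tfs_class")
  if (is.null(seed)) {
    idnum <- suppressWarnings(as.integer(gsub("\\D", "", record$id[1] %||% "0")))
    if (is.na(idnum)) idnum <- 0L
    seed <- (pspec$seed + 7919L * idnum) %% .Machine$integer.max
  }
  i <- if (cls == "early") 1L else 2L
  with_seed(seed, {
    shape <- pspec$shape
    vox <- pspec$bg_mean + pspec$bg_sd * correlated_field(shape, pspec$bg_corr)
    mask <- voi_template(shape, pspec$voi_radius_frac)
    if (!any(mask)) stop_radonset("VOI template is empty for this shape")

    ## lesion = the ellipsoidal core of the VOI holding `extent` of its volume
    extent <- pspec$extent_base +
      pspec$extent_slope * (10 - record$aspects[1]) / 10
    if (extent <= 0) stop_radonset("lesion extent rule yields an empty lesion")
    idx <- which(mask, arr.ind = TRUE)
    ctr <- colMeans(idx)
    semi <- c(1, 0.8, 0.7)  # ellipsoid anisotropy
    d <- sqrt(((idx[, 1] - ctr[1]) / semi[1])^2 +
              ((idx[, 2] - ctr[2]) / semi[2])^2 +
              ((idx[, 3] - ctr[3]) / semi[3])^2)
    n_lesion <- max(1L, round(extent * nrow(idx)))
    lesion_rows <- order(d)[seq_len(n_lesion)]
    lesion <- array(FALSE, shape)
    lesion[idx[lesion_rows, , drop = FALSE]] <- TRUE

    vox[lesion] <- vox[lesion] - pspec$decrement[i] +
      pspec$het_sd[i] * correlated_field(shape, pspec$het_corr[i])[lesion]
    list(volume = ct_volume(vox, pspec$spacing),
         mask = voi_mask(mask, pspec$spacing), lesion = lesion)
  })
}

## Logical-array shift by integer offset d, FALSE-padded.
#' @noRd
shift_logical <- function(m, d) {
  dm <- dim(m)
  out <- array(FALSE, dm)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      src[[ax]] <- seq_len(dm[ax] - d[ax])
      dst[[ax]] <- src[[ax]] + d[ax]
    } else {
      src[[ax]] <- seq_len(dm[ax] + d[ax]) - d[ax]
      dst[[ax]] <- src[[ax]] + d[ax]
    }
    if (length(src[[ax]]) == 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

#' Perturb a VOI mask (synthetic second rater)
#'
#' Emulates inter-rater segmentation variability by flipping boundary-layer
#' voxels under a spatially correlated noise field: inner-boundary voxels
#' are removed and outer-boundary voxels added, each with probability
#' `magnitude`. `magnitude = 0` returns the mask unchanged; the expected
#' Dice overlap with the input decreases monotonically in `magnitude`.
#'
#' @param mask A [voi_mask].
#' @param magnitude Flip probability per boundary voxel, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A perturbed [voi_mask] on the same grid.
#' @export
perturb_mask <- function(mask, magnitude, seed = .radonset_default_seed) {
  stopifnot(inherits(mask, "voi_mask"))
  check_number(magnitude, "magnitude", 0, 1)
  if (magnitude == 0) return(mask)
  m <- mask$voxels
  with_seed(seed, {
    shifts <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    shifts <- shifts[rowSums(abs(shifts)) > 0, ]
    nb <- array(FALSE, dim(m))   # has an out-of-mask neighbour
    nbm <- array(FALSE, dim(m))  # has an in-mask neighbour
    for (r in seq_len(nrow(shifts))) {
      s <- shift_logical(m, as.integer(shifts[r, ]))
      nb <- nb | !s
      nbm <- nbm | s
    }
    inner <- m & nb      # mask voxels touching background (incl. volume edge)
    outer <- !m & nbm    # background voxels touching the mask
    eta <- pnorm(correlated_field(dim(m), 3))
    out <- m
    out[inner & (eta < magnitude)] <- FALSE
    out[outer & (eta > 1 - magnitude)] <- TRUE
    if (!any(out)) stop_radonset("perturbation emptied the mask")
    voi_mask(out, mask$spacing)
  })
}

#' Dice overlap between two masks
#'
#' @param a,b [voi_mask] objects on the same grid.
#' @return Dice coefficient `2|A & B| / (|A| + |B|)`.
#' @export
dice_overlap <- function(a, b) {
  stopifnot(inherits(a, "voi_mask"), inherits(b, "voi_mask"),
            identical(dim(a$voxels), dim(b$voxels)))
  2 * sum(a$voxels & b$voxels) / (sum(a$voxels) + sum(b$voxels))
}
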