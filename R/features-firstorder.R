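## First-order (histogram) and shape (formfactor) feature families.

#' @noRd
nearest_rank_percentile <- function(xs, p) {
  ## nearest-rank (inverse-CDF) percentile: the ceil(p/100 * n)-th order
  ## statistic of the sorted sample
  n <- length(xs)
  xs[pmax(1L, ceiling(p / 100 * n))]
}

#' First-order histogram features of the in-mask intensities
#'
#' Computes 42 first-order statistics: 21 summary statistics and the 21
#' nearest-rank percentiles \{1, 5, 10, ..., 95, 99\}. `Entropy`,
#' `Uniformity` and `Mode` are computed from an equal-width histogram with
#' `n_bins` bins over `breaks` (default: the observed in-mask range).
#' Moments use the population (divisor n) convention; a constant region has
#' `StandardDeviation` 0, `Entropy` 0 and `Uniformity` 1.
#'
#' @param volume A [ct_volume], or directly a numeric vector of in-mask
#'   values (then `mask` may be `NULL`).
#' @param mask A [voi_mask] aligned with `volume`.
#' @param n_bins Histogram bins for the entropy/uniformity/mode estimates.
#' @param breaks Optional explicit bin edges (length `n_bins + 1`),
#'   e.g. `seq(0, 1, length.out = n_bins + 1)` for windowed intensities.
#' @return Named numeric vector of length 42.
#' @export
histogram_features <- function(volume, mask = NULL, n_bins = 64L, breaks = NULL) {
  x <- if (inherits(volume, "ct_volume")) {
    stopifnot(inherits(mask, "voi_mask"))
    check_aligned(volume, mask)
    volume$voxels[mask$voxels]
  } else as.numeric(volume)
  n <- length(x)
  if (n == 0L) stop_radonset("empty mask: no in-mask intensities")

  if (is.null(breaks)) {
    rng <- range(x)
    breaks <- if (rng[1] == rng[2]) c(rng[1] - 0.5, rng[1] + 0.5)
              else seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  h <- hist(x, breaks = breaks, plot = FALSE, include.lowest = TRUE)
  p <- h$counts / n
  pp <- p[p > 0]

  xs <- sort(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  med <- median(x)
  p10 <- nearest_rank_percentile(xs, 10)
  p90 <- nearest_rank_percentile(xs, 90)
  mid <- x[x >= p10 & x <= p90]

  pcts <- c(1, seq(5, 95, by = 5), 99)
  pvals <- vapply(pcts, function(q) nearest_rank_percentile(xs, q), numeric(1))
  names(pvals) <- paste0("Percentile", pcts)

  c(Min = xs[1],
    Max = xs[n],
    Range = xs[n] - xs[1],
    Mean = mu,
    Median = med,
    Mode = h$mids[which.max(h$counts)],
    StandardDeviation = sqrt(m2),
    Variance = m2,
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RootMeanSquare = sqrt(mean(x^2)),
    Energy = sum(x^2),
    Entropy = -sum(pp * log2(pp)),
    Uniformity = sum(p^2),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    CoefficientOfVariation = if (mu != 0) sqrt(m2) / mu else 0,
    InterquartileRange = nearest_rank_percentile(xs, 75) -
      nearest_rank_percentile(xs, 25),
    RobustMeanAbsoluteDeviation =
      if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    Percentile10to90Mean = if (length(mid)) mean(mid) else mu,
    TotalExcessOverMedian = sum(pmax(x - med, 0)),
    VoxelCount = n,
    pvals)
}

## Count exposed voxel faces along each axis; returns per-axis face counts.
#' @noRd
exposed_faces <- function(m) {
  vapply(1:3, function(ax) {
    up <- shift_logical(m, c(ax == 1, ax == 2, ax == 3) * 1L)
    dn <- shift_logical(m, c(ax == 1, ax == 2, ax == 3) * -1L)
    sum(m & !up) + sum(m & !dn)
  }, numeric(1))
}

## Largest pairwise distance between rows of a coordinate matrix. The
## maximizing pair lies on the convex hull, and every hull vertex is an
## axis-extremal point of its grid line, so large sets are first reduced
## exactly to the per-line min/max points along each axis.
#' @noRd
max_pairwise_distance <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(0)
  if (n > 2000L) {
    keep <- logical(n)
    for (a in 1:3) {
      b <- setdiff(1:3, a)
      key <- paste(pts[, b[1]], pts[, b[2]])
      ord <- order(key, pts[, a])
      keep[ord[!duplicated(key[ord])]] <- TRUE
      keep[ord[!duplicated(key[ord], fromLast = TRUE)]] <- TRUE
    }
    pts <- pts[keep, , drop = FALSE]
  }
  max(dist(pts))
}

#' Shape (formfactor) features of a VOI mask
#'
#' Surface area uses exposed-voxel-face counting: every mask voxel face not
#' shared with another mask voxel contributes its physical face area. The
#' maximum 3D diameter is the largest Euclidean distance between voxel
#' centres (computed over the surface voxels). Compactness and sphericity
#' follow the usual surface/volume forms: `Compactness1 = V / (sqrt(pi) *
#' A^(3/2))`, `Compactness2 = 36 * pi * V^2 / A^3`, `Sphericity =
#' (36 * pi * V^2)^(1/3) / A`, `SphericalDisproportion = 1 / Sphericity`.
#'
#' @param mask A [voi_mask] (its `spacing` gives the physical units).
#' @param spacing Optional spacing override (mm).
#' @return Named numeric vector of length 9: `Volume` (mm^3), `VoxelCount`,
#'   `SurfaceArea` (mm^2), `SurfaceToVolumeRatio`, `Compactness1`,
#'   `Compactness2`, `Sphericity`, `SphericalDisproportion`,
#'   `Maximum3DDiameter` (mm).
#' @examples
#' m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
#' shape_features(voi_mask(m))  # unit cube: SurfaceArea 6, Volume 1
#' @export
shape_features <- function(mask, spacing = NULL) {
  stopifnot(inherits(mask, "voi_mask"))
  sp <- spacing %||% mask$spacing
  m <- mask$voxels
  nvox <- sum(m)
  volume <- nvox * prod(sp)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  area <- sum(exposed_faces(m) * face_area)

  ## surface voxels suffice for the maximum diameter
  surf <- m
  inner <- m
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    d <- integer(3); d[ax] <- s
    inner <- inner & shift_logical(m, d)
  }
  surf <- m & !inner
  if (!any(surf)) surf <- m
  pts <- arrayInd(which(surf), dim(m))
  pts <- sweep(pts, 2, sp, "*")
  maxd <- max_pairwise_distance(pts)

  sph <- (36 * pi * volume^2)^(1 / 3) / area
  c(Volume = volume,
    VoxelCount = nvox,
    SurfaceArea = area,
    SurfaceToVolumeRatio = area / volume,
    Compactness1 = volume / (sqrt(pi) * area^1.5),
    Compactness2 = 36 * pi * volume^2 / area^3,
    Sphericity = sph,
    SphericalDisproportion = 1 / sph,
    Maximum3DDiameter = maxd)
}
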