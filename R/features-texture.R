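## Texture feature families on the discretized VOI: gray-level
## co-occurrence (GLCM), classic Haralick statistics, run-length (RLM) and
## size-zone (GLSZM) matrices.
##
## Directions are the four in-plane angles (0, 45, 90, 135 degrees) applied
## within each axial slice and accumulated across slices; at 45/135 degrees
## a displacement of `offset` means `offset` steps of the unit lattice
## vector (chessboard metric). The RLM `offset` is the sampling step of the
## ray: rays are sampled every `step` voxels and maximal same-level in-mask
## runs of consecutive samples are counted (step 1 is the classic
## run-length matrix).

## In-plane unit displacement for each angle, as (dx, dy).
#' @noRd
angle_unit <- function(angle) {
  switch(as.character(angle),
         "0"   = c(1L, 0L),
         "45"  = c(1L, 1L),
         "90"  = c(0L, 1L),
         "135" = c(-1L, 1L),
         stop_radonset("angle must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Pairs of in-mask voxels separated by `offset` steps of the unit lattice
#' vector at `angle`, within each axial slice, accumulated over slices,
#' symmetrized, and normalized to probabilities.
#'
#' @param disc A `discretized_voi` (see [discretize_gray_levels()]).
#' @param angle One of 0, 45, 90, 135 (degrees, in-plane).
#' @param offset Positive integer displacement (voxels).
#' @return Object of class `cooccurrence_matrix`: list with `p` (n_bins x
#'   n_bins probability matrix) and `n_pairs` (ordered pair count).
#' @examples
#' lev <- array(0L, c(3, 3, 1))
#' lev[, , 1] <- matrix(c(1, 1, 2, 1, 2, 2, 3, 3, 3), 3, byrow = TRUE)
#' d <- structure(list(levels = lev, n_bins = 3L, spacing = c(1, 1, 1),
#'                     mask = lev > 0), class = "discretized_voi")
#' cooccurrence_matrix(d, 0, 1)$p * 12  # symmetrized pair counts
#' @export
cooccurrence_matrix <- function(disc, angle, offset = 1L) {
  stopifnot(inherits(disc, "discretized_voi"))
  if (offset < 1L) stop_radonset("offset must be >= 1")
  u <- angle_unit(angle) * as.integer(offset)
  lev <- disc$levels
  d <- dim(lev)
  nb <- disc$n_bins
  ## overlap region of the volume and its shifted copy
  xr <- if (u[1] >= 0) seq_len(max(0L, d[1] - u[1])) else
    seq_len(max(0L, d[1] + u[1])) - u[1]
  yr <- if (u[2] >= 0) seq_len(max(0L, d[2] - u[2])) else
    seq_len(max(0L, d[2] + u[2])) - u[2]
  if (!length(xr) || !length(yr))
    stop_radonset("undefined co-occurrence matrix: no valid pairs")
  a <- lev[xr, yr, , drop = FALSE]
  b <- lev[xr + u[1], yr + u[2], , drop = FALSE]
  keep <- a > 0L & b > 0L
  a <- a[keep]; b <- b[keep]
  if (!length(a)) stop_radonset("undefined co-occurrence matrix: no valid pairs")
  counts <- matrix(tabulate((a - 1L) * nb + b, nbins = nb * nb), nb, nb,
                   byrow = TRUE)
  counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), n_pairs = sum(counts)),
            class = "cooccurrence_matrix")
}

#' @noRd
glcm_marginals <- function(p) {
  nb <- nrow(p)
  i <- seq_len(nb)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(i * px); muy <- sum(i * py)
  sx <- sqrt(sum((i - mux)^2 * px)); sy <- sqrt(sum((i - muy)^2 * py))
  list(i = i, px = px, py = py, mux = mux, muy = muy, sx = sx, sy = sy)
}

#' Co-occurrence (GLCM) features
#'
#' Eight features of one co-occurrence matrix: `Energy`, `Entropy` (base-2,
#' with 0 log 0 := 0), `Inertia`, `Correlation`,
#' `InverseDifferenceMoment`, `ClusterShade`, `ClusterProminence` and
#' `HaralickCorrelation`. When a marginal variance is zero, `Correlation`
#' and `HaralickCorrelation` are returned as 0 and the result carries a
#' `degenerate` attribute.
#'
#' @param m A [cooccurrence_matrix()].
#' @return Named numeric vector of length 8.
#' @export
glcm_features <- function(m) {
  stopifnot(inherits(m, "cooccurrence_matrix"))
  p <- m$p
  g <- glcm_marginals(p)
  I <- matrix(g$i, nrow(p), ncol(p))
  J <- t(I)
  pp <- p[p > 0]
  degen <- g$sx == 0 || g$sy == 0
  corr <- if (degen) 0 else sum((I - g$mux) * (J - g$muy) * p) / (g$sx * g$sy)
  hcorr <- if (degen) 0 else (sum(I * J * p) - g$mux * g$muy) / (g$sx * g$sy)
  out <- c(Energy = sum(p^2),
           Entropy = -sum(pp * log2(pp)),
           Inertia = sum((I - J)^2 * p),
           Correlation = corr,
           InverseDifferenceMoment = sum(p / (1 + (I - J)^2)),
           ClusterShade = sum((I + J - g$mux - g$muy)^3 * p),
           ClusterProminence = sum((I + J - g$mux - g$muy)^4 * p),
           HaralickCorrelation = hcorr)
  if (degen) attr(out, "degenerate") <- TRUE
  out
}

#' Classic Haralick features
#'
#' The ten classic Haralick statistics of the offset-1 co-occurrence
#' matrices, computed per angle and averaged over the four in-plane angles:
#' angular second moment, contrast, correlation, sum-of-squares variance,
#' inverse difference moment, sum average, sum entropy, sum variance,
#' difference entropy and difference variance (entropies base-2).
#'
#' @param disc A `discretized_voi`.
#' @return Named numeric vector of length 10.
#' @export
haralick_features <- function(disc) {
  per_angle <- lapply(c(0, 45, 90, 135), function(a) {
    m <- tryCatch(cooccurrence_matrix(disc, a, 1L), error = function(e) NULL)
    if (is.null(m)) return(NULL)
    p <- m$p
    g <- glcm_marginals(p)
    nb <- nrow(p)
    I <- matrix(g$i, nb, nb); J <- t(I)
    pp <- p[p > 0]
    ## distributions of i + j (2..2N) and |i - j| (0..N-1)
    psum <- vapply(2:(2 * nb), function(k) sum(p[I + J == k]), numeric(1))
    pdif <- vapply(0:(nb - 1), function(k) sum(p[abs(I - J) == k]), numeric(1))
    ks <- 2:(2 * nb); kd <- 0:(nb - 1)
    sum_avg <- sum(ks * psum)
    mud <- sum(kd * pdif)
    corr <- if (g$sx == 0 || g$sy == 0) 0
            else sum((I - g$mux) * (J - g$muy) * p) / (g$sx * g$sy)
    c(AngularSecondMoment = sum(p^2),
      Contrast = sum((I - J)^2 * p),
      Correlation = corr,
      SumOfSquaresVariance = sum((I - g$mux)^2 * p),
      InverseDifferenceMoment = sum(p / (1 + (I - J)^2)),
      SumAverage = sum_avg,
      SumEntropy = -sum(psum[psum > 0] * log2(psum[psum > 0])),
      SumVariance = sum((ks - sum_avg)^2 * psum),
      DifferenceEntropy = -sum(pdif[pdif > 0] * log2(pdif[pdif > 0])),
      DifferenceVariance = sum((kd - mud)^2 * pdif))
  })
  per_angle <- per_angle[!vapply(per_angle, is.null, logical(1))]
  if (!length(per_angle))
    stop_radonset("undefined co-occurrence matrices at all angles")
  Reduce("+", per_angle) / length(per_angle)
}

#' Run-length matrix
#'
#' For each axial slice, lattice rays along `angle` are sampled every
#' `step` voxels and maximal same-level in-mask runs of consecutive samples
#' are counted. `step = 1` gives the classic run-length matrix; an
#' out-of-mask sample breaks a run.
#'
#' @param disc A `discretized_voi`.
#' @param angle One of 0, 45, 90, 135.
#' @param step Positive integer sampling step of the ray.
#' @return Object of class `run_length_matrix`: list with `R` (n_bins x
#'   max-run-length count matrix) and `Nr` (total runs).
#' @export
run_length_matrix <- function(disc, angle, step = 1L) {
  stopifnot(inherits(disc, "discretized_voi"))
  if (step < 1L) stop_radonset("step must be >= 1")
  u <- angle_unit(angle)
  lev <- disc$levels
  d <- dim(lev)
  ids <- which(lev > 0L)
  if (!length(ids)) stop_radonset("no in-mask samples")
  co <- arrayInd(ids, d)
  x <- co[, 1]; y <- co[, 2]; z <- co[, 3]
  ## parameter t advances by `step` along the ray; c indexes parallel rays
  if (identical(u, c(1L, 0L)))       { t <- x; cc <- y }
  else if (identical(u, c(0L, 1L)))  { t <- y; cc <- x }
  else if (identical(u, c(1L, 1L)))  { t <- x; cc <- y - x }
  else                               { t <- y; cc <- x + y }
  phase <- t %% step
  k <- t %/% step
  ray <- (((z - 1) * (max(cc) - min(cc) + 1) + (cc - min(cc))) * step) + phase
  g <- lev[ids]
  ord <- order(ray, k)
  ray <- ray[ord]; k <- k[ord]; g <- g[ord]
  ## voxels whose t is not a multiple of `step` along their phase are still
  ## valid samples: every voxel belongs to exactly one (phase-shifted) ray
  newrun <- c(TRUE, diff(ray) != 0 | diff(k) != 1 | diff(g) != 0)
  run_id <- cumsum(newrun)
  rl <- tabulate(run_id)
  rg <- g[newrun]
  maxr <- max(rl)
  nb <- disc$n_bins
  R <- matrix(tabulate((rg - 1L) * maxr + rl, nbins = nb * maxr), nb, maxr,
              byrow = TRUE)
  structure(list(R = R, Nr = sum(R)), class = "run_length_matrix")
}

#' Run-length (RLM) features
#'
#' Ten weighted-sum features of a run-length matrix `R(g, r)` with total
#' run count `Nr`: short/long run emphasis, gray-level and run-length
#' non-uniformity, low/high gray-level run emphasis, and the four combined
#' short/long x low/high emphases.
#'
#' @param m A [run_length_matrix()].
#' @return Named numeric vector of length 10.
#' @export
rlm_features <- function(m) {
  stopifnot(inherits(m, "run_length_matrix"))
  R <- m$R; Nr <- m$Nr
  if (Nr <= 0) stop_radonset("run-length matrix holds no runs")
  G <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  L <- t(matrix(seq_len(ncol(R)), ncol(R), nrow(R)))
  c(ShortRunEmphasis = sum(R / L^2) / Nr,
    LongRunEmphasis = sum(R * L^2) / Nr,
    GreyLevelNonuniformity = sum(rowSums(R)^2) / Nr,
    RunLengthNonuniformity = sum(colSums(R)^2) / Nr,
    LowGreyLevelRunEmphasis = sum(R / G^2) / Nr,
    HighGreyLevelRunEmphasis = sum(R * G^2) / Nr,
    ShortRunLowGreyLevelEmphasis = sum(R / (G^2 * L^2)) / Nr,
    ShortRunHighGreyLevelEmphasis = sum(R * G^2 / L^2) / Nr,
    LongRunLowGreyLevelEmphasis = sum(R * L^2 / G^2) / Nr,
    LongRunHighGreyLevelEmphasis = sum(R * G^2 * L^2) / Nr)
}

## 26-connected labelling of equal-level in-mask voxels: build the
## equal-level adjacency edge list over the 13 positive lattice offsets and
## take graph components. Returns an integer array with component ids
## 1..K in-mask and 0 outside.
#' @noRd
label_zones <- function(lev) {
  d <- dim(lev)
  n <- prod(d)
  ids <- which(lev > 0L)
  vid <- integer(n)
  vid[ids] <- seq_along(ids)
  li <- array(seq_len(n), d)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[1:13, , drop = FALSE]  # one of each +/- pair
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    u <- offs[r, ]
    xr <- if (u[1] >= 0) seq_len(d[1] - u[1]) else seq_len(d[1] + u[1]) - u[1]
    yr <- if (u[2] >= 0) seq_len(d[2] - u[2]) else seq_len(d[2] + u[2]) - u[2]
    zr <- if (u[3] >= 0) seq_len(d[3] - u[3]) else seq_len(d[3] + u[3]) - u[3]
    if (!length(xr) || !length(yr) || !length(zr)) next
    la <- lev[xr, yr, zr, drop = FALSE]
    lb <- lev[xr + u[1], yr + u[2], zr + u[3], drop = FALSE]
    eq <- which(la == lb & la > 0L)
    if (!length(eq)) next
    ia <- li[xr, yr, zr, drop = FALSE][eq]
    ib <- li[xr + u[1], yr + u[2], zr + u[3], drop = FALSE][eq]
    edges[[r]] <- rbind(vid[ia], vid[ib])
  }
  el <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (!is.null(el) && length(el))
    g <- igraph::add_edges(g, as.vector(el))
  comp <- igraph::components(g)$membership
  lab <- array(0L, d)
  lab[ids] <- as.integer(comp)
  lab
}

#' Gray-level size-zone matrix
#'
#' Zones are maximal 26-connected (3D) components of equal-level in-mask
#' voxels; `Z(g, s)` counts zones of level `g` and size `s` voxels.
#'
#' @param disc A `discretized_voi`.
#' @return Object of class `size_zone_matrix`: list with `Z`, `Nz` (total
#'   zones) and `n_voxels` (in-mask voxel count).
#' @export
size_zone_matrix <- function(disc) {
  stopifnot(inherits(disc, "discretized_voi"))
  lev <- disc$levels
  if (!any(lev > 0L)) stop_radonset("empty mask")
  lab <- label_zones(lev)
  ids <- which(lab > 0L)
  comp <- lab[ids]
  zs <- tabulate(comp)
  zg <- lev[ids[match(seq_along(zs), comp)]]
  nb <- disc$n_bins
  maxs <- max(zs)
  Z <- matrix(tabulate((zg - 1L) * maxs + zs, nbins = nb * maxs), nb, maxs,
              byrow = TRUE)
  structure(list(Z = Z, Nz = sum(Z), n_voxels = length(ids)),
            class = "size_zone_matrix")
}

#' Size-zone (GLSZM) features
#'
#' Eleven features following the run-length formula pattern with
#' `(gray level g, zone size s)`, plus `ZonePercentage = Nz / n_voxels`.
#'
#' @param m A [size_zone_matrix()].
#' @return Named numeric vector of length 11.
#' @export
glszm_features <- function(m) {
  stopifnot(inherits(m, "size_zone_matrix"))
  Z <- m$Z; Nz <- m$Nz
  if (Nz <= 0) stop_radonset("size-zone matrix holds no zones")
  G <- matrix(seq_len(nrow(Z)), nrow(Z), ncol(Z))
  S <- t(matrix(seq_len(ncol(Z)), ncol(Z), nrow(Z)))
  c(SmallZoneEmphasis = sum(Z / S^2) / Nz,
    LargeZoneEmphasis = sum(Z * S^2) / Nz,
    GreyLevelNonuniformity = sum(rowSums(Z)^2) / Nz,
    ZoneSizeNonuniformity = sum(colSums(Z)^2) / Nz,
    ZonePercentage = Nz / m$n_voxels,
    LowGreyLevelZoneEmphasis = sum(Z / G^2) / Nz,
    HighGreyLevelZoneEmphasis = sum(Z * G^2) / Nz,
    SmallZoneLowGreyLevelEmphasis = sum(Z / (G^2 * S^2)) / Nz,
    SmallZoneHighGreyLevelEmphasis = sum(Z * G^2 / S^2) / Nz,
    LargeZoneLowGreyLevelEmphasis = sum(Z * S^2 / G^2) / Nz,
    LargeZoneHighGreyLevelEmphasis = sum(Z * G^2 * S^2) / Nz)
}

#' Aggregate per-angle feature values over all directions
#'
#' @param values Numeric vector of per-angle values (one per angle).
#' @return `c(mean, SD)` where `SD` is the population (divisor n) standard
#'   deviation. Any non-finite input propagates `NA` with an `undefined`
#'   attribute.
#' @export
aggregate_directions <- function(values) {
  if (any(!is.finite(values))) {
    out <- c(mean = NA_real_, SD = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  mu <- mean(values)
  c(mean = mu, SD = sqrt(mean((values - mu)^2)))
}
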