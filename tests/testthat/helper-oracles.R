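# Independent brute-force oracles for the texture/shape/histogram feature
# families: explicit nested-loop enumeration of pairs, runs, zones and
# voxel faces, kept deliberately naive and separate from the package's
# vectorized implementations.

oracle_unit <- function(angle) {
  switch(as.character(angle), "0" = c(1, 0), "45" = c(1, 1),
         "90" = c(0, 1), "135" = c(-1, 1))
}

# co-occurrence counts by looping over every voxel pair
oracle_glcm <- function(lev, angle, offset, n_bins) {
  u <- oracle_unit(angle) * offset
  d <- dim(lev)
  counts <- matrix(0, n_bins, n_bins)
  for (z in seq_len(d[3])) for (x in seq_len(d[1])) for (y in seq_len(d[2])) {
    x2 <- x + u[1]; y2 <- y + u[2]
    if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2]) next
    a <- lev[x, y, z]; b <- lev[x2, y2, z]
    if (a > 0 && b > 0) {
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts
}

oracle_glcm_features <- function(counts) {
  if (sum(counts) == 0) stop("no pairs")
  p <- counts / sum(counts)
  nb <- nrow(p)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum((1:nb) * px); muy <- sum((1:nb) * py)
  sx <- sqrt(sum(((1:nb) - mux)^2 * px)); sy <- sqrt(sum(((1:nb) - muy)^2 * py))
  e <- ent <- inertia <- corr <- idm <- cs <- cp <- hc <- 0
  for (i in 1:nb) for (j in 1:nb) {
    pij <- p[i, j]
    e <- e + pij^2
    if (pij > 0) ent <- ent - pij * log2(pij)
    inertia <- inertia + (i - j)^2 * pij
    idm <- idm + pij / (1 + (i - j)^2)
    cs <- cs + (i + j - mux - muy)^3 * pij
    cp <- cp + (i + j - mux - muy)^4 * pij
    if (sx > 0 && sy > 0) {
      corr <- corr + (i - mux) * (j - muy) * pij / (sx * sy)
      hc <- hc + i * j * pij
    }
  }
  hc <- if (sx > 0 && sy > 0) (hc - mux * muy) / (sx * sy) else 0
  c(Energy = e, Entropy = ent, Inertia = inertia, Correlation = corr,
    InverseDifferenceMoment = idm, ClusterShade = cs, ClusterProminence = cp,
    HaralickCorrelation = hc)
}

# run enumeration: walk every ray sample-by-sample
oracle_rlm <- function(lev, angle, step, n_bins) {
  u <- oracle_unit(angle)
  d <- dim(lev)
  runs <- list()
  for (z in seq_len(d[3])) {
    seen <- matrix(FALSE, d[1], d[2])  # sample already part of a walked ray
    for (x0 in seq_len(d[1])) for (y0 in seq_len(d[2])) {
      if (seen[x0, y0]) next
      # walk back to the ray start for this phase
      x <- x0; y <- y0
      while (x - u[1] * step >= 1 && x - u[1] * step <= d[1] &&
             y - u[2] * step >= 1 && y - u[2] * step <= d[2]) {
        x <- x - u[1] * step; y <- y - u[2] * step
      }
      g <- 0; len <- 0
      while (x >= 1 && x <= d[1] && y >= 1 && y <= d[2]) {
        seen[x, y] <- TRUE
        v <- lev[x, y, z]
        if (v > 0 && v == g) len <- len + 1
        else {
          if (g > 0) runs[[length(runs) + 1]] <- c(g, len)
          g <- v; len <- if (v > 0) 1 else 0
          if (v == 0) g <- 0
        }
        x <- x + u[1] * step; y <- y + u[2] * step
      }
      if (g > 0) runs[[length(runs) + 1]] <- c(g, len)
    }
  }
  if (!length(runs)) stop("no runs")
  maxr <- max(vapply(runs, `[`, numeric(1), 2))
  R <- matrix(0, n_bins, maxr)
  for (r in runs) R[r[1], r[2]] <- R[r[1], r[2]] + 1
  R
}

oracle_rlm_features <- function(R) {
  Nr <- sum(R)
  out <- c(ShortRunEmphasis = 0, LongRunEmphasis = 0,
           GreyLevelNonuniformity = 0, RunLengthNonuniformity = 0,
           LowGreyLevelRunEmphasis = 0, HighGreyLevelRunEmphasis = 0,
           ShortRunLowGreyLevelEmphasis = 0, ShortRunHighGreyLevelEmphasis = 0,
           LongRunLowGreyLevelEmphasis = 0, LongRunHighGreyLevelEmphasis = 0)
  for (g in seq_len(nrow(R))) for (r in seq_len(ncol(R))) {
    v <- R[g, r]
    out["ShortRunEmphasis"] <- out["ShortRunEmphasis"] + v / r^2
    out["LongRunEmphasis"] <- out["LongRunEmphasis"] + v * r^2
    out["LowGreyLevelRunEmphasis"] <- out["LowGreyLevelRunEmphasis"] + v / g^2
    out["HighGreyLevelRunEmphasis"] <- out["HighGreyLevelRunEmphasis"] + v * g^2
    out["ShortRunLowGreyLevelEmphasis"] <-
      out["ShortRunLowGreyLevelEmphasis"] + v / (g^2 * r^2)
    out["ShortRunHighGreyLevelEmphasis"] <-
      out["ShortRunHighGreyLevelEmphasis"] + v * g^2 / r^2
    out["LongRunLowGreyLevelEmphasis"] <-
      out["LongRunLowGreyLevelEmphasis"] + v * r^2 / g^2
    out["LongRunHighGreyLevelEmphasis"] <-
      out["LongRunHighGreyLevelEmphasis"] + v * g^2 * r^2
  }
  for (g in seq_len(nrow(R)))
    out["GreyLevelNonuniformity"] <- out["GreyLevelNonuniformity"] + sum(R[g, ])^2
  for (r in seq_len(ncol(R)))
    out["RunLengthNonuniformity"] <- out["RunLengthNonuniformity"] + sum(R[, r])^2
  out / Nr
}

# zone enumeration by breadth-first flood fill over the 26-neighbourhood
oracle_glszm <- function(lev, n_bins) {
  d <- dim(lev)
  visited <- array(FALSE, d)
  zones <- list()
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (visited[x, y, z] || lev[x, y, z] == 0) next
    g <- lev[x, y, z]
    queue <- list(c(x, y, z)); visited[x, y, z] <- TRUE; size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (any(q < 1) || any(q > d)) next
        if (!visited[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == g) {
          visited[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  maxs <- max(vapply(zones, `[`, numeric(1), 2))
  Z <- matrix(0, n_bins, maxs)
  for (zn in zones) Z[zn[1], zn[2]] <- Z[zn[1], zn[2]] + 1
  Z
}

oracle_glszm_features <- function(Z, n_voxels) {
  Nz <- sum(Z)
  sze <- lze <- gln <- zsn <- lglze <- hglze <- szlge <- szhge <- lzlge <- lzhge <- 0
  for (g in seq_len(nrow(Z))) for (s in seq_len(ncol(Z))) {
    v <- Z[g, s]
    sze <- sze + v / s^2; lze <- lze + v * s^2
    lglze <- lglze + v / g^2; hglze <- hglze + v * g^2
    szlge <- szlge + v / (g^2 * s^2); szhge <- szhge + v * g^2 / s^2
    lzlge <- lzlge + v * s^2 / g^2; lzhge <- lzhge + v * g^2 * s^2
  }
  for (g in seq_len(nrow(Z))) gln <- gln + sum(Z[g, ])^2
  for (s in seq_len(ncol(Z))) zsn <- zsn + sum(Z[, s])^2
  c(SmallZoneEmphasis = sze / Nz, LargeZoneEmphasis = lze / Nz,
    GreyLevelNonuniformity = gln / Nz, ZoneSizeNonuniformity = zsn / Nz,
    ZonePercentage = Nz / n_voxels,
    LowGreyLevelZoneEmphasis = lglze / Nz,
    HighGreyLevelZoneEmphasis = hglze / Nz,
    SmallZoneLowGreyLevelEmphasis = szlge / Nz,
    SmallZoneHighGreyLevelEmphasis = szhge / Nz,
    LargeZoneLowGreyLevelEmphasis = lzlge / Nz,
    LargeZoneHighGreyLevelEmphasis = lzhge / Nz)
}

# exposed-face surface area and exhaustive maximum diameter
oracle_shape <- function(mask, spacing) {
  d <- dim(mask)
  area <- 0
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  pts <- NULL
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z]) next
    pts <- rbind(pts, c(x, y, z) * spacing)
    nb <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
    for (k in seq_along(nb)) {
      q <- c(x, y, z) + nb[[k]]
      outside <- any(q < 1) || any(q > d) || !mask[q[1], q[2], q[3]]
      if (outside) area <- area + face[ceiling(k / 2)]
    }
  }
  maxd <- 0
  if (nrow(pts) > 1)
    for (i in 1:(nrow(pts) - 1)) for (j in (i + 1):nrow(pts))
      maxd <- max(maxd, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  nvox <- sum(mask)
  vol <- nvox * prod(spacing)
  list(SurfaceArea = area, Volume = vol, VoxelCount = nvox,
       Maximum3DDiameter = maxd)
}

# small random discretized volume (levels 1..n_bins inside a random mask)
random_disc <- function(seed, n_bins = 4L) {
  set.seed(seed)
  d <- c(sample(2:6, 2, replace = TRUE), sample(1:3, 1))
  lev <- array(sample(seq_len(n_bins), prod(d), replace = TRUE), d)
  mask <- array(runif(prod(d)) < 0.75, d)
  if (!any(mask)) mask[1, 1, 1] <- TRUE
  lev[!mask] <- 0L
  structure(list(levels = lev, n_bins = n_bins, spacing = c(1, 1, 1),
                 mask = lev > 0L), class = "discretized_voi")
}

# the worked 3x3 single-slice fixture; listed rows run along the angle-0
# direction (array dim 1)
fixture_3x3 <- function() {
  lev <- array(0L, c(3, 3, 1))
  lev[, , 1] <- matrix(c(1, 1, 2, 1, 2, 2, 3, 3, 3), 3)
  structure(list(levels = lev, n_bins = 3L, spacing = c(1, 1, 1),
                 mask = lev > 0L), class = "discretized_voi")
}

make_disc <- function(lev, n_bins) {
  structure(list(levels = lev, n_bins = as.integer(n_bins),
                 spacing = c(1, 1, 1), mask = lev > 0L),
            class = "discretized_voi")
}

# naive first-order statistics (population moments, nearest-rank
# percentiles, explicit histogram counting with 64 equal-width bins over
# the observed range)
oracle_histogram <- function(x, n_bins = 64L) {
  n <- length(x)
  xs <- sort(x)
  pct <- function(p) xs[max(1, ceiling(p / 100 * n))]
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  med <- if (n %% 2 == 1) xs[(n + 1) / 2] else (xs[n / 2] + xs[n / 2 + 1]) / 2
  lo <- xs[1]; hi <- xs[n]
  if (lo == hi) { edges <- c(lo - 0.5, lo + 0.5); nb <- 1L }
  else { edges <- seq(lo, hi, length.out = n_bins + 1); nb <- n_bins }
  counts <- integer(nb)
  for (v in x) {
    b <- 1L
    while (b < nb && v > edges[b + 1]) b <- b + 1L
    counts[b] <- counts[b] + 1L
  }
  p <- counts / n
  ent <- 0
  for (q in p) if (q > 0) ent <- ent - q * log2(q)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  p10 <- pct(10); p90 <- pct(90)
  mid_vals <- x[x >= p10 & x <= p90]
  out <- c(Min = lo, Max = hi, Range = hi - lo, Mean = mu, Median = med,
           Mode = mids[which.max(counts)],
           StandardDeviation = sqrt(m2), Variance = m2,
           MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
           RootMeanSquare = sqrt(sum(x^2) / n), Energy = sum(x^2),
           Entropy = ent, Uniformity = sum(p^2),
           Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
           Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
           CoefficientOfVariation = if (mu != 0) sqrt(m2) / mu else 0,
           InterquartileRange = pct(75) - pct(25),
           RobustMeanAbsoluteDeviation =
             sum(abs(mid_vals - mean(mid_vals))) / length(mid_vals),
           Percentile10to90Mean = mean(mid_vals),
           TotalExcessOverMedian = sum(pmax(x - med, 0)),
           VoxelCount = n)
  for (q in c(1, seq(5, 95, 5), 99))
    out[paste0("Percentile", q)] <- pct(q)
  out
}
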