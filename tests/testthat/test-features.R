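test_that("first-order features on closed-form samples", {
  h <- histogram_features(1:10)
  expect_equal(unname(h["Percentile20"]), 2)
  expect_equal(unname(h["Mean"]), 5.5)
  expect_equal(unname(h["Median"]), 5.5)
  expect_equal(unname(h["Min"]), 1)
  expect_equal(unname(h["Max"]), 10)
  expect_equal(unname(h["VoxelCount"]), 10)
  expect_equal(unname(h["InterquartileRange"]),
               sort(1:10)[ceiling(7.5)] - sort(1:10)[ceiling(2.5)])

  const <- histogram_features(rep(4, 25))
  expect_equal(unname(const["StandardDeviation"]), 0)
  expect_equal(unname(const["Entropy"]), 0)
  expect_equal(unname(const["Uniformity"]), 1)
  expect_equal(unname(const["Skewness"]), 0)
})

test_that("nearest-rank percentiles match their definition on random samples", {
  set.seed(3)
  for (rep in 1:20) {
    x <- rnorm(sample(5:60, 1))
    xs <- sort(x)
    h <- histogram_features(x)
    for (p in c(1, 20, 50, 95, 99))
      expect_equal(unname(h[paste0("Percentile", p)]),
                   xs[max(1, ceiling(p / 100 * length(x)))])
  }
})

test_that("shape features on hand-countable masks", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  s <- shape_features(voi_mask(m))
  expect_equal(unname(s["SurfaceArea"]), 6)
  expect_equal(unname(s["Volume"]), 1)
  expect_equal(unname(s["Maximum3DDiameter"]), 0)

  m2 <- array(FALSE, c(4, 3, 3)); m2[2:3, 2, 2] <- TRUE
  s2 <- shape_features(voi_mask(m2))
  expect_equal(unname(s2["SurfaceArea"]), 10)
  expect_equal(unname(s2["Volume"]), 2)
  expect_equal(unname(s2["Maximum3DDiameter"]), 1)
})

test_that("digital ball approaches the face-counting sphericity limit", {
  ## face-counted surface of a digitized ball converges to 1.5x the
  ## analytic sphere area, so Sphericity tends to 2/3
  d <- rep(41L, 3); ctr <- 21; r <- 17
  g <- expand.grid(x = 1:41, y = 1:41, z = 1:41)
  ball <- array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= r^2, d)
  s <- shape_features(voi_mask(ball))
  expect_equal(unname(s["Volume"]), 4 / 3 * pi * r^3, tolerance = 0.02)
  expect_equal(unname(s["Sphericity"]), 2 / 3, tolerance = 0.05)
  expect_equal(unname(s["Maximum3DDiameter"]), 2 * r, tolerance = 0.03)
})

test_that("worked 3x3 co-occurrence example is matched exactly", {
  d <- fixture_3x3()
  m <- cooccurrence_matrix(d, 0, 1)
  expect_equal(m$n_pairs, 12)
  expect_equal(m$p[1, 1], 2 / 12)
  expect_equal(m$p[1, 2], 2 / 12)
  expect_equal(m$p[2, 1], 2 / 12)
  expect_equal(m$p[2, 2], 2 / 12)
  expect_equal(m$p[3, 3], 4 / 12)
  f <- glcm_features(m)
  expect_equal(unname(f["Inertia"]), 1 / 3)
  expect_equal(unname(f["ClusterShade"]), 1)
})

test_that("degenerate co-occurrence cases behave as specified", {
  const <- make_disc(array(2L, c(3, 3, 2)), 4L)
  m <- cooccurrence_matrix(const, 0, 1)
  expect_equal(m$p[2, 2], 1)
  f <- glcm_features(m)
  expect_equal(unname(f["Energy"]), 1)
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Inertia"]), 0)
  expect_equal(unname(f["InverseDifferenceMoment"]), 1)
  expect_equal(unname(f["Correlation"]), 0)   # degenerate marginals
  expect_true(isTRUE(attr(f, "degenerate")))
  expect_error(cooccurrence_matrix(const, 0, 50), "no valid pairs")
})

test_that("worked 3x3 run-length example is matched exactly", {
  d <- fixture_3x3()
  m <- run_length_matrix(d, 0, 1)
  expect_equal(m$Nr, 5)
  f <- rlm_features(m)
  expect_equal(unname(f["LongRunEmphasis"]), 3.8)
  expect_equal(unname(f["LongRunLowGreyLevelEmphasis"]), 1.45)

  row <- make_disc(array(1L, c(7, 1, 1)), 2L)
  mr <- run_length_matrix(row, 0, 1)
  expect_equal(mr$Nr, 1)
  expect_equal(mr$R[1, 7], 1)

  alt <- make_disc(array(rep(c(1L, 2L), 4)[1:8], c(8, 1, 1)), 2L)
  ma <- run_length_matrix(alt, 0, 1)
  expect_equal(ma$Nr, 8)
  fa <- rlm_features(ma)
  expect_equal(unname(fa["ShortRunEmphasis"]), 1)
  expect_equal(unname(fa["LongRunEmphasis"]), 1)
})

test_that("worked 3x3 size-zone example is matched exactly", {
  d <- fixture_3x3()
  m <- size_zone_matrix(d)
  expect_equal(m$Nz, 3)
  expect_true(all(m$Z[, 3] == c(1, 1, 1)))
  f <- glszm_features(m)
  expect_equal(unname(f["ZonePercentage"]), 1 / 3)
  expect_equal(unname(f["SmallZoneEmphasis"]), 1 / 9)
  expect_equal(unname(f["LargeZoneEmphasis"]), 9)

  const <- make_disc(array(3L, c(4, 3, 2)), 4L)
  mc <- size_zone_matrix(const)
  expect_equal(mc$Nz, 1)
  expect_equal(unname(glszm_features(mc)["ZonePercentage"]), 1 / 24)
})

test_that("haralick contrast equals the mean per-angle co-occurrence inertia", {
  for (s in 1:5) {
    d <- random_disc(s, n_bins = 5L)
    har <- tryCatch(haralick_features(d), error = function(e) NULL)
    if (is.null(har)) next
    inert <- vapply(c(0, 45, 90, 135), function(a)
      tryCatch(unname(glcm_features(cooccurrence_matrix(d, a, 1))["Inertia"]),
               error = function(e) NA_real_), numeric(1))
    expect_equal(unname(har["Contrast"]), mean(inert, na.rm = TRUE),
                 tolerance = 1e-12)
    expect_gte(unname(har["SumEntropy"]), 0)
  }
  const <- make_disc(array(2L, c(3, 3, 1)), 4L)
  hc <- haralick_features(const)
  expect_equal(unname(hc["Contrast"]), 0)
  expect_equal(unname(hc["AngularSecondMoment"]), 1)
})

test_that("co-occurrence matrices are symmetric and normalized", {
  for (s in 1:20) {
    d <- random_disc(s)
    for (a in c(0, 45, 90, 135)) {
      m <- tryCatch(cooccurrence_matrix(d, a, 1), error = function(e) NULL)
      if (is.null(m)) next
      expect_equal(m$p, t(m$p))
      expect_equal(sum(m$p), 1)
    }
  }
})

test_that("texture matrices match brute-force enumeration on random volumes", {
  for (s in 1:15) {
    d <- random_disc(s)
    for (a in c(0, 45, 90, 135)) for (k in 1:2) {
      counts <- oracle_glcm(d$levels, a, k, d$n_bins)
      imp <- tryCatch(cooccurrence_matrix(d, a, k), error = function(e) NULL)
      if (sum(counts) == 0) { expect_null(imp); next }
      expect_equal(imp$p, counts / sum(counts), tolerance = 1e-12)

      R <- tryCatch(oracle_rlm(d$levels, a, k, d$n_bins),
                    error = function(e) NULL)
      rimp <- tryCatch(run_length_matrix(d, a, k), error = function(e) NULL)
      if (is.null(R)) { expect_null(rimp); next }
      pad <- function(M, nc) cbind(M, matrix(0, nrow(M), nc - ncol(M)))
      nc <- max(ncol(R), ncol(rimp$R))
      expect_equal(pad(rimp$R, nc), pad(R, nc), ignore_attr = TRUE)
    }
    Z <- oracle_glszm(d$levels, d$n_bins)
    zimp <- size_zone_matrix(d)
    expect_equal(zimp$Z, Z, ignore_attr = TRUE)
    ## zone sizes partition the in-mask voxels
    S <- t(matrix(seq_len(ncol(zimp$Z)), ncol(zimp$Z), nrow(zimp$Z)))
    expect_equal(sum(zimp$Z * S), sum(d$mask))
  }
})

test_that("direction aggregation returns the mean and population SD", {
  expect_equal(aggregate_directions(c(2, 2, 2, 2)), c(mean = 2, SD = 0))
  agg <- aggregate_directions(c(1, 2, 3, 4))
  expect_equal(unname(agg["mean"]), 2.5)
  expect_equal(unname(agg["SD"]), sqrt(1.25), tolerance = 1e-9)
  und <- aggregate_directions(c(1, NA, 3, 4))
  expect_true(all(is.na(und)))
  expect_true(isTRUE(attr(und, "undefined")))
})

test_that("default extraction yields the deterministic 396-name grid", {
  nm <- feature_names_default()
  expect_length(nm, 396)
  expect_equal(anyDuplicated(nm), 0L)
  rec <- data.frame(id = "S0001", tfs_class = "early", aspects = 7)
  ph <- generate_phantom(rec, phantom_spec(shape = c(24L, 24L, 24L)), seed = 4)
  fv <- extract_features(ph$volume, ph$mask)
  fv2 <- extract_features(ph$volume, ph$mask)
  expect_identical(fv, fv2)
  expect_equal(names(fv), nm)
  expect_true(all(is.finite(fv)))
})

test_that("a 90-degree in-plane rotation permutes the angle features", {
  set.seed(9)
  n <- 10
  lev <- array(sample(1:6, n * n * 2, replace = TRUE), c(n, n, 2))
  d <- make_disc(lev, 6L)
  rot <- array(0L, dim(lev))
  for (z in 1:2) rot[, , z] <- t(lev[, , z])[, n:1]  # 90-degree rotation
  dr <- make_disc(rot, 6L)

  for (fam in c("glcm", "rlm")) {
    get <- function(dd, a) {
      if (fam == "glcm") glcm_features(cooccurrence_matrix(dd, a, 1))
      else rlm_features(run_length_matrix(dd, a, 1))
    }
    expect_equal(get(d, 0), get(dr, 90), tolerance = 1e-9)
    expect_equal(get(d, 90), get(dr, 0), tolerance = 1e-9)
    expect_equal(get(d, 45), get(dr, 135), tolerance = 1e-9)
    expect_equal(get(d, 135), get(dr, 45), tolerance = 1e-9)
    mean0 <- Reduce("+", lapply(c(0, 45, 90, 135), function(a) get(d, a))) / 4
    mean1 <- Reduce("+", lapply(c(0, 45, 90, 135), function(a) get(dr, a))) / 4
    expect_equal(mean0, mean1, tolerance = 1e-9)
  }
})

test_that("bin-aligned intensity shifts keep structural texture features", {
  set.seed(11)
  nb <- 16L
  lev <- array(sample(3:10, 5 * 5 * 2, replace = TRUE), c(5, 5, 2))
  d1 <- make_disc(lev, nb)
  d2 <- make_disc(lev + 3L, nb)  # shift by 3 bins, still within 1..nb
  f1 <- glcm_features(cooccurrence_matrix(d1, 0, 1))
  f2 <- glcm_features(cooccurrence_matrix(d2, 0, 1))
  expect_equal(f1, f2, tolerance = 1e-12)  # all 8 depend on level differences

  keep <- c("ShortRunEmphasis", "LongRunEmphasis", "GreyLevelNonuniformity",
            "RunLengthNonuniformity")
  r1 <- rlm_features(run_length_matrix(d1, 0, 1))
  r2 <- rlm_features(run_length_matrix(d2, 0, 1))
  expect_equal(r1[keep], r2[keep], tolerance = 1e-12)

  zkeep <- c("SmallZoneEmphasis", "LargeZoneEmphasis",
             "GreyLevelNonuniformity", "ZoneSizeNonuniformity",
             "ZonePercentage")
  z1 <- glszm_features(size_zone_matrix(d1))
  z2 <- glszm_features(size_zone_matrix(d2))
  expect_equal(z1[zkeep], z2[zkeep], tolerance = 1e-12)
})
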