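# exhaustive pair-counting AUC with ties counted 1/2
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == "early"]; neg <- scores[labels == "late"]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

test_that("DeLong AUC matches the worked placement-value example", {
  scores <- c(0.9, 0.4, 0.5, 0.1)
  labels <- c("early", "early", "late", "late")
  r <- auc_delong(scores, labels)
  expect_equal(r$auc, 0.75)
  expect_equal(r$se^2, 0.125, tolerance = 1e-12)

  perfect <- auc_delong(c(3, 4, 1, 2), c("early", "early", "late", "late"))
  expect_equal(perfect$auc, 1)
  allties <- auc_delong(rep(1, 6), rep(c("early", "late"), 3))
  expect_equal(allties$auc, 0.5)
  expect_true(all(r$ci >= 0 & r$ci <= 1) && r$ci[1] <= r$auc &&
                r$auc <= r$ci[2])
})

test_that("DeLong AUC equals exhaustive pair counting on small datasets", {
  set.seed(21)
  for (rep in 1:30) {
    n <- sample(4:30, 1)
    labels <- c("early", "late",
                sample(c("early", "late"), n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)  # induce ties
    expect_equal(auc_delong(scores, labels)$auc, pair_count_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("Youden point maximizes J with the specified tie-breaks", {
  r <- auc_delong(c(0.9, 0.4, 0.5, 0.1), c("early", "early", "late", "late"))
  op <- youden_point(r)
  expect_equal(op$youden, 0.5)
  ## J = 0.5 is attained at both ends of the four-point ROC; the tie rule
  ## (higher sensitivity first) selects the sensitive end
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 0.5)
  expect_true(any(abs(r$curve$sensitivity + r$curve$specificity - 1.5) < 1e-12 &
                    r$curve$threshold > 0.5))

  perfect <- youden_point(auc_delong(c(3, 4, 1, 2),
                                     c("early", "early", "late", "late")))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  flat <- youden_point(auc_delong(rep(1, 6), rep(c("early", "late"), 3)))
  expect_equal(flat$youden, 0)
})

test_that("paired DeLong comparison: identity, symmetry and power", {
  set.seed(22)
  labels <- rep(c("early", "late"), c(20, 25))
  a <- rnorm(45)
  same <- delong_compare(a, a, labels)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  b <- rnorm(45)
  expect_equal(delong_compare(a, b, labels)$p, delong_compare(b, a, labels)$p)

  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    y <- rep(c(1, 0), c(200, 300))
    info <- y * 1.2 + rnorm(500)
    noise <- rnorm(500)
    p <- delong_compare(info, noise, ifelse(y == 1, "early", "late"))$p
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 47L)
})

test_that("McNemar: worked examples and equivalence with binomial enumeration", {
  labels <- rep("early", 10)
  expect_equal(mcnemar_compare(labels, labels, labels)$p, 1)

  ## b = 0, c = 8
  labs <- rep("early", 8)
  pa <- rep("early", 8); pb <- rep("late", 8)
  res <- mcnemar_compare(pb, pa, labs)   # A always wrong, B always right
  expect_equal(res$p, 2 * 0.5^8)

  ## b = 5, c = 5 via construction
  labs2 <- rep("early", 10)
  pa2 <- rep(c("early", "late"), each = 5)
  pb2 <- rep(c("late", "early"), each = 5)
  expect_equal(mcnemar_compare(pa2, pb2, labs2)$p, 1)

  ## exact p equals brute-force two-sided binomial enumeration for b+c <= 12
  for (bc in 1:12) for (b in 0:bc) {
    labs3 <- rep("early", bc)
    pa3 <- rep(c("early", "late"), c(b, bc - b))
    pb3 <- rep(c("late", "early"), c(b, bc - b))
    got <- mcnemar_compare(pa3, pb3, labs3)$p
    dens <- dbinom(0:bc, bc, 0.5)
    brute <- sum(dens[dens <= dbinom(b, bc, 0.5) + 1e-12])
    expect_equal(got, brute, tolerance = 1e-9)
  }
})

test_that("decision curve: worked value, comparator limits and invariants", {
  labels <- rep(c("early", "late"), c(46, 77))
  probs <- c(rep(0.99, 46), rep(0.01, 77))  # perfect probabilities
  d <- decision_curve(probs, labels)
  expect_equal(d$curve$nb_model[d$curve$pt == 0.5], 46 / 123, tolerance = 1e-12)
  expect_true(all(d$curve$nb_none == 0))
  expect_equal(d$curve$nb_all[1], 46 / 123 - (77 / 123) * 0.01 / 0.99,
               tolerance = 1e-12)
  expect_true(all(d$curve$nb_model <= d$prevalence + 1e-12))
  expect_true(all(d$curve$nb_all <= d$prevalence + 1e-12))
  ## perfect probabilities are beneficial across essentially the whole grid
  expect_false(is.null(d$range))
  expect_lte(d$range[1], 0.03)
  expect_equal(d$range[2], 0.99)
})

test_that("informative models earn much longer beneficial ranges than null ones", {
  len <- function(d) if (is.null(d$range)) 0 else diff(d$range)
  set.seed(23)
  null_len <- vapply(1:25, function(s) {
    y <- rbinom(123, 1, 46 / 123)
    len(decision_curve(runif(123), ifelse(y == 1, "early", "late")))
  }, numeric(1))
  info_len <- vapply(1:25, function(s) {
    y <- rbinom(123, 1, 46 / 123)
    pr <- plogis(-0.5 + 2.5 * y + rnorm(123))
    len(decision_curve(pr, ifelse(y == 1, "early", "late")))
  }, numeric(1))
  expect_gt(mean(info_len), 4 * mean(null_len))
})

test_that("ICC forms: identity, variance-ratio recovery and degeneracy", {
  x <- rnorm(30, 10, 2)
  expect_equal(icc_agreement(cbind(x, x), "inter")$icc, 1)
  expect_equal(icc_agreement(cbind(x, x), "intra")$icc, 1)

  set.seed(24)
  subj <- rnorm(500, 0, 1)
  ratings <- cbind(subj + rnorm(500), subj + rnorm(500))
  expect_equal(icc_agreement(ratings, "inter")$icc, 0.5, tolerance = 0.05)

  flat <- cbind(rep(1, 10), rep(1, 10))
  res <- icc_agreement(flat, "inter")
  expect_equal(res$icc, 0)
  expect_true(res$degenerate)
  expect_error(icc_agreement(cbind(1:3, 1:3)), "5 subjects")
})

test_that("Spearman feature-clinical correlations respect rank invariance", {
  set.seed(25)
  age <- rnorm(120, 72, 12)
  feats <- data.frame(pos = exp(age / 30), neg = -age, noise = rnorm(120))
  out <- spearman_feature_clinical(feats, data.frame(age = age))
  expect_equal(out$rho["pos", "age"], 1)
  expect_equal(out$rho["neg", "age"], -1)
  expect_equal(out$p["pos", "age"], 0)

  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    n <- 123
    a <- rnorm(n)
    f <- -0.218 * a + sqrt(1 - 0.218^2) * rnorm(n)  # target rho ~ -0.218
    r <- spearman_feature_clinical(data.frame(f = f), data.frame(a = a))
    if (r$rho["f", "a"] < 0) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("constant columns are flagged in the correlation matrix", {
  expect_warning(
    out <- spearman_feature_clinical(data.frame(f = rep(1, 10)),
                                     data.frame(age = rnorm(10))),
    "constant column")
  expect_true(is.na(out$rho["f", "age"]))
})

test_that("mask perturbation degrades feature reliability monotonically", {
  ps <- phantom_spec(shape = c(20L, 20L, 20L))
  cohort <- generate_cohort(cohort_spec(n_early = 4, n_late = 4), seed = 26)
  cfg <- extract_config(offsets = c(1L, 2L))
  pairs <- lapply(seq_len(nrow(cohort)), function(i)
    generate_phantom(cohort[i, ], ps, seed = 100 + i))
  base <- lapply(pairs, function(p) extract_features(p$volume, p$mask, cfg))
  med_icc <- vapply(c(0.05, 0.4), function(mag) {
    pert <- lapply(seq_along(pairs), function(i) {
      m2 <- perturb_mask(pairs[[i]]$mask, mag, seed = 200 + i)
      extract_features(pairs[[i]]$volume, m2, cfg)
    })
    ta <- as.data.frame(do.call(rbind, base))
    tb <- as.data.frame(do.call(rbind, pert))
    keep <- vapply(ta, stats::sd, numeric(1)) > 0
    icc_features(ta[, keep], tb[, keep], mode = "inter")$median
  }, numeric(1))
  expect_gt(med_icc[1], med_icc[2])
})
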