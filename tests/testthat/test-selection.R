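test_that("standardization uses the population-SD convention", {
  out <- standardize_features(data.frame(f = c(1, 2, 3)))
  expect_equal(out$table$f, c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(unname(out$params$mean["f"]), 2)
  expect_equal(unname(out$params$sd["f"]), sqrt(2 / 3))
})

test_that("degenerate features are excluded and re-application is refused", {
  df <- data.frame(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(out <- standardize_features(df), "zero-variance")
  expect_equal(names(out$params$mean), "a")
  expect_equal(out$params$dropped, "b")
  expect_error(apply_standardization(out$params, out$table),
               "already standardized")
})

test_that("development parameters transfer unchanged to validation rows", {
  set.seed(4)
  dev <- data.frame(f = rnorm(50, 10, 3), g = rnorm(50))
  val <- data.frame(f = rnorm(20, 10, 3), g = rnorm(20))
  out <- standardize_features(dev)
  zval <- apply_standardization(out$params, val)
  expect_equal(zval$f, (val$f - mean(dev$f)) /
                 sqrt(mean((dev$f - mean(dev$f))^2)))
  expect_equal(colMeans(out$table), c(f = 0, g = 0), tolerance = 1e-12)
  expect_equal(apply(out$table, 2, function(x) sqrt(mean((x - mean(x))^2))),
               c(f = 1, g = 1), tolerance = 1e-12)
})

test_that("univariate filter: null features fail, separated features pass", {
  labels <- rep(c("early", "late"), c(20, 30))
  same <- data.frame(f = rep(seq_len(10), 5))
  rep1 <- univariate_filter(same, labels)
  expect_false(rep1$pass)
  expect_gt(rep1$p, 0.5)

  ## the exact Mann-Whitney branch: {1,2,3} vs {4,5,6} gives p = 0.1
  expect_equal(suppressWarnings(wilcox.test(1:3, 4:6)$p.value), 0.1)

  for (s in 1:10) {
    set.seed(s)
    x <- c(rnorm(50, 3), rnorm(50, 0))  # Cohen's d = 3
    rep2 <- univariate_filter(data.frame(f = x),
                              rep(c("early", "late"), each = 50))
    expect_true(rep2$pass)
  }
  expect_error(univariate_filter(same, rep("early", 50)), "two classes")
})

test_that("normality routing chooses t for normal and Mann-Whitney for skewed data", {
  set.seed(5)
  labels <- rep(c("early", "late"), each = 60)
  norm_f <- data.frame(f = rnorm(120))
  skew_f <- data.frame(f = rlnorm(120, 0, 1.5))
  expect_equal(univariate_filter(norm_f, labels)$test, "t")
  expect_equal(univariate_filter(skew_f, labels)$test, "mann-whitney")
})

test_that("univariate type-I rate on null features is close to alpha", {
  set.seed(6)
  labels <- rep(c("early", "late"), c(46, 77))
  total <- 0L; tests <- 0L
  for (s in 1:200) {
    tab <- as.data.frame(matrix(rnorm(123 * 20), 123))
    rep <- univariate_filter(tab, labels)
    total <- total + sum(rep$pass); tests <- tests + nrow(rep)
  }
  rate <- total / tests
  se <- sqrt(0.05 * 0.95 / tests)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("redundancy filter removes rank-equivalent duplicates only", {
  set.seed(7)
  n <- 200
  a <- rnorm(n)
  tab <- data.frame(A = a, B = exp(a), C = rnorm(n))  # B monotone in A
  labels <- ifelse(a + rnorm(n) > 0, "early", "late")
  rep <- univariate_filter(tab, labels, alpha = 1)  # all pass
  surv <- redundancy_filter(tab, rep, rho_max = 0.9)
  expect_length(intersect(surv, c("A", "B")), 1L)
  expect_true("C" %in% surv)

  dup <- data.frame(A = a, A2 = a)
  repd <- univariate_filter(dup, labels, alpha = 1)
  expect_length(redundancy_filter(dup, repd), 1L)

  indep <- as.data.frame(matrix(rnorm(n * 10), n))
  repi <- univariate_filter(indep, labels, alpha = 1)
  expect_length(redundancy_filter(indep, repi), 10L)
})

test_that("fully penalized LASSO returns the prevalence intercept", {
  set.seed(8)
  sim <- simulate_signal_table(n = 120, n_informative = 3, n_noise = 7)
  std <- standardize_features(sim$features)
  res <- lasso_select(std$table, sim$labels, lambda = c(50, 40, 30))
  expect_length(res$coefficients, 0)
  prev <- mean(sim$labels == "early")
  expect_equal(res$intercept, qlogis(prev), tolerance = 1e-6)
})

test_that("LASSO selection is deterministic given the fold seed", {
  sim <- simulate_signal_table(n = 150, n_informative = 4, n_noise = 26)
  std <- standardize_features(sim$features)
  a <- lasso_select(std$table, sim$labels, seed = 21)
  b <- lasso_select(std$table, sim$labels, seed = 21)
  expect_identical(a$lambda_min, b$lambda_min)
  expect_identical(a$coefficients, b$coefficients)
  expect_true(a$lambda_min %in% a$lambda)
  expect_equal(a$cvm[which(a$lambda == a$lambda_min)], min(a$cvm))
})

test_that("the unpenalized limit agrees with maximum-likelihood logistic", {
  set.seed(9)
  n <- 400
  x <- matrix(rnorm(n * 3), n)
  colnames(x) <- c("a", "b", "c")
  y <- rbinom(n, 1, plogis(0.5 * x[, 1] - 0.8 * x[, 2]))
  labels <- ifelse(y == 1, "early", "late")
  res <- lasso_select(as.data.frame(x), labels,
                      lambda = c(1e-6, 1e-8, 1e-10), thresh = 1e-14)
  ml <- glm(y ~ x, family = binomial())
  expect_equal(unname(res$coefficients[c("a", "b", "c")]),
               unname(coef(ml)[-1]), tolerance = 1e-4)
  expect_equal(res$intercept, unname(coef(ml)[1]), tolerance = 1e-4)
})

test_that("LASSO recovers planted signal features", {
  hits <- 0L
  for (s in 1:20) {
    sim <- simulate_signal_table(n = 300, seed = s)
    std <- standardize_features(sim$features)
    las <- suppressWarnings(lasso_select(std$table, sim$labels, seed = s))
    if (sum(sim$informative %in% names(las$coefficients)) >= 4) hits <- hits + 1L
  }
  expect_gte(hits, 16L)
})

test_that("cascade stages are monotone: each survivor set nests the next", {
  sim <- simulate_signal_table(n = 200, n_informative = 5, n_noise = 45,
                               seed = 31)
  std <- standardize_features(sim$features)
  uni <- univariate_filter(std$table, sim$labels)
  surv <- redundancy_filter(std$table, uni)
  las <- suppressWarnings(
    lasso_select(std$table[, surv, drop = FALSE], sim$labels, seed = 31))
  expect_true(all(surv %in% uni$feature[uni$pass]))
  expect_true(all(names(las$coefficients) %in% surv))
})
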