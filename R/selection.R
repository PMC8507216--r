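## Feature-selection cascade: standardization (development-cohort
## parameters only), univariate filtering (normality-routed t test or
## Mann-Whitney U), greedy Spearman redundancy elimination, and
## L1-penalized logistic selection with seeded stratified 10-fold
## cross-validation at the deviance-minimizing penalty.

#' Standardize a feature table
#'
#' Estimates per-feature mean and population SD on the development table
#' and returns the z-scored table together with the parameters, which must
#' be re-used unchanged on validation/external data via
#' [apply_standardization()]. Zero-variance and non-finite features are
#' excluded with a warning.
#'
#' @param table Numeric data.frame/matrix of features (rows = subjects).
#' @return A list with `params` (class `standardization_params`: `mean`,
#'   `sd`, `dropped`) and `table` (the standardized data.frame).
#' @examples
#' standardize_features(data.frame(f = c(1, 2, 3)))$table$f
#' @export
standardize_features <- function(table) {
  x <- as.matrix(table)
  if (!nrow(x)) stop_radonset("empty feature table")
  mu <- colMeans(x)
  sdv <- sqrt(colMeans(sweep(x, 2, mu)^2))
  bad <- !is.finite(mu) | !is.finite(sdv) | sdv <= 0
  if (any(bad))
    warning(sprintf("excluding %d zero-variance or non-finite feature(s): %s",
                    sum(bad), paste(head(colnames(x)[bad], 5), collapse = ", ")),
            call. = FALSE)
  params <- structure(list(mean = mu[!bad], sd = sdv[!bad],
                           dropped = colnames(x)[bad]),
                      class = "standardization_params")
  list(params = params, table = apply_standardization(params, table))
}

#' Apply development-cohort standardization to a feature table
#'
#' @param params A `standardization_params` object from
#'   [standardize_features()].
#' @param table Feature table containing at least the retained features.
#' @return Data.frame of z-scored retained features (same row order).
#' @export
apply_standardization <- function(params, table) {
  stopifnot(inherits(params, "standardization_params"))
  keep <- names(params$mean)
  miss <- setdiff(keep, colnames(table))
  if (length(miss))
    stop_radonset("table lacks standardized feature(s): ",
                  paste(head(miss, 5), collapse = ", "))
  x <- as.matrix(table[, keep, drop = FALSE])
  if (!is.null(attr(table, "radonset_standardized")))
    stop_radonset("table is already standardized; re-apply to the raw table")
  out <- as.data.frame(sweep(sweep(x, 2, params$mean), 2, params$sd, "/"))
  attr(out, "radonset_standardized") <- TRUE
  out
}

## Normality-routed two-sample test: Shapiro-Wilk in each class at 0.05
## decides equal-variance t versus Mann-Whitney (exact when feasible,
## tie-corrected normal approximation otherwise).
#' @noRd
route_two_sample <- function(x, labels) {
  g1 <- x[labels == levels(labels)[1]]
  g2 <- x[labels == levels(labels)[2]]
  normal <- function(v) {
    if (length(unique(v)) < 3L) return(FALSE)
    n <- length(v)
    if (n > 5000L) v <- v[seq(1, n, length.out = 5000L)]
    shapiro.test(v)$p.value >= 0.05
  }
  if (stats::sd(x) == 0)
    return(list(test = "degenerate", p = 1))
  if (normal(g1) && normal(g2)) {
    list(test = "t", p = t.test(g1, g2, var.equal = TRUE)$p.value)
  } else {
    list(test = "mann-whitney",
         p = suppressWarnings(wilcox.test(g1, g2)$p.value))
  }
}

#' Univariate feature filter
#'
#' Per feature, Shapiro-Wilk normality within each class (at 0.05) routes
#' the comparison to an equal-variance two-sample t test (both classes
#' normal) or a Mann-Whitney U test; features with `p < alpha` pass.
#'
#' @param table Feature table (rows = subjects).
#' @param labels TFS labels (see Details in [radonset()]); two classes with
#'   at least 3 subjects each.
#' @param alpha Significance level (default 0.05).
#' @return A data.frame of class `univariate_report`: `feature`, `test`,
#'   `p`, `pass`, ordered as the input columns.
#' @export
univariate_filter <- function(table, labels, alpha = 0.05) {
  labels <- as_tfs_label(labels)
  if (nlevels(droplevels(labels)) < 2L || any(table(labels) < 3L))
    stop_radonset("need two classes with at least 3 subjects each")
  res <- lapply(colnames(table), function(f) {
    r <- route_two_sample(as.numeric(table[[f]]), labels)
    data.frame(feature = f, test = r$test, p = r$p, pass = r$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("univariate_report", class(out))
  out
}

#' Spearman redundancy filter
#'
#' Greedy elimination of mutually correlated features: candidates are
#' ordered by ascending univariate p (ties broken lexicographically by
#' name) and accepted iff their absolute Spearman correlation with every
#' already-accepted feature stays below `rho_max`.
#'
#' @param table Feature table (raw or standardized; Spearman is
#'   rank-based so either works).
#' @param report A [univariate_filter()] report; only passing features are
#'   considered.
#' @param rho_max Redundancy threshold (default 0.9).
#' @return Character vector of surviving feature names.
#' @export
redundancy_filter <- function(table, report, rho_max = 0.9) {
  stopifnot(inherits(report, "univariate_report"))
  check_number(rho_max, "rho_max", 0, 1)
  cand <- report[report$pass, , drop = FALSE]
  if (!nrow(cand)) stop_radonset("no features passed the univariate filter")
  cand <- cand[order(cand$p, cand$feature), , drop = FALSE]
  ranks <- apply(table[, cand$feature, drop = FALSE], 2, rank)
  kept <- character(0)
  for (f in cand$feature) {
    if (!length(kept)) { kept <- f; next }
    rho <- suppressWarnings(cor(ranks[, f], ranks[, kept, drop = FALSE]))
    if (all(abs(rho) < rho_max, na.rm = TRUE)) kept <- c(kept, f)
  }
  kept
}

## Stratified fold assignment, deterministic given the seed.
#' @noRd
stratified_folds <- function(labels, n_folds, seed) {
  foldid <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  })
  foldid
}

#' LASSO logistic feature selection
#'
#' Fits an L1-penalized logistic regression of the (standardized) feature
#' table on the TFS class over a descending lambda grid (100 log-spaced
#' values spanning 4 decades below the data-derived maximal lambda) and
#' selects the grid minimizer of the mean 10-fold cross-validated binomial
#' deviance, with folds stratified by class and fixed by `seed`.
#'
#' @param table Standardized feature table.
#' @param labels TFS labels (positive class `early`).
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer fold seed (recorded in the result).
#' @param lambda Optional explicit lambda grid override.
#' @param ... Further arguments passed to [glmnet::cv.glmnet()] (e.g.
#'   `thresh`).
#' @return A list of class `lasso_result`: `lambda` (grid), `cvm` (mean CV
#'   deviance per lambda), `lambda_min`, `intercept`, `coefficients`
#'   (named, nonzero only), `fold_seed`, `fit` (the glmnet path).
#' @export
lasso_select <- function(table, labels, n_folds = 10L,
                         seed = .radonset_default_seed, lambda = NULL, ...) {
  labels <- as_tfs_label(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop_radonset("labels hold a single class")
  x <- as.matrix(table)
  y <- as.integer(labels == "early")
  foldid <- stratified_folds(labels, n_folds, seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial",
                          type.measure = "deviance", foldid = foldid,
                          lambda = lambda, nlambda = 100,
                          lambda.min.ratio = 1e-4, standardize = FALSE, ...)
  beta <- coef(cv$glmnet.fit, s = cv$lambda.min)
  coefs <- as.numeric(beta)[-1]
  names(coefs) <- rownames(beta)[-1]
  structure(list(lambda = cv$lambda, cvm = cv$cvm,
                 lambda_min = cv$lambda.min,
                 intercept = as.numeric(beta)[1],
                 coefficients = coefs[coefs != 0],
                 fold_seed = as.integer(seed), fit = cv$glmnet.fit),
            class = "lasso_result")
}

#' Simulate a feature table with a known class signal
#'
#' Generates a cohort-level feature table for selection/recovery studies:
#' `n_informative` standardized features carry a linear log-odds signal of
#' size `effect` each toward the early class, `n_noise` features are pure
#' standard normal noise, and (optionally) age and ASPECTS covariates are
#' drawn from the default clinical generator with their own log-odds
#' contributions. Class labels are drawn from the logistic model, so the
#' true generating model is known.
#'
#' @param n Number of subjects.
#' @param n_informative,n_noise Feature counts (defaults 6 and 94).
#' @param effect Log-odds slope per informative feature (default 0.5).
#' @param clinical Include `age`/`aspects` columns with log-odds effects
#'   `+0.03 * (age - 72)` and `+0.15 * (aspects - 7)` (early-class
#'   patients are older with higher ASPECTS; default FALSE).
#' @param seed Integer seed.
#' @return A list with `features` (data.frame `F1..`), `labels` (factor),
#'   `informative` (names of signal features), and if `clinical`, a
#'   `covariates` data.frame.
#' @export
simulate_signal_table <- function(n = 300L, n_informative = 6L,
                                  n_noise = 94L, effect = 0.5,
                                  clinical = FALSE,
                                  seed = .radonset_default_seed) {
  with_seed(seed, {
    p <- n_informative + n_noise
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- paste0("F", seq_len(p))
    eta <- x[, seq_len(n_informative), drop = FALSE] %*%
      rep(effect, n_informative)
    cov <- NULL
    if (clinical) {
      age <- rtruncnorm(n, 72, 13, 18, 100)
      aspects <- sample(0:10, n, replace = TRUE, prob = .aspects_pmf_late)
      eta <- eta + 0.03 * (age - 72) + 0.15 * (aspects - 7)
      cov <- data.frame(age = age, aspects = aspects)
    }
    y <- rbinom(n, 1, plogis(as.numeric(eta)))
    out <- list(features = as.data.frame(x),
                labels = as_tfs_label(y),
                informative = paste0("F", seq_len(n_informative)))
    if (clinical) out$covariates <- cov
    out
  })
}
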