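## Rad-score and combined clinicoradiological model.
##
## The rad-score is the linear predictor of the penalized logistic model
## over the selected standardized features (optionally refit unpenalized);
## the combined model is an ordinary maximum-likelihood logistic regression
## of the TFS class on the rad-score plus the screened clinical variables.

#' Compute rad-scores
#'
#' `score = intercept + sum(coef_k * standardized feature_k)`. Features are
#' standardized with the development-cohort parameters carried by the
#' model, so validation subjects never contribute to the scaling.
#'
#' @param model A `radscore_model` (list with `intercept`, `coefficients`,
#'   `standardization`, `source`), usually taken from a [radonset()] fit.
#' @param features Feature table (raw, unstandardized) containing every
#'   model feature.
#' @return Numeric vector of rad-scores (one per row).
#' @export
compute_radscore <- function(model, features) {
  need <- names(model$coefficients)
  miss <- setdiff(need, colnames(features))
  if (length(miss))
    stop_radonset("missing model feature(s): ", paste(miss, collapse = ", "))
  if (!length(need))
    return(rep(model$intercept, nrow(features)))
  z <- apply_standardization(model$standardization, features)
  as.numeric(model$intercept +
               as.matrix(z[, need, drop = FALSE]) %*% model$coefficients)
}

#' Screen clinicoradiological variables for association with TFS class
#'
#' Continuous variables (`age`, `nihss`) are routed by within-class
#' Shapiro-Wilk normality to an equal-variance t test or Mann-Whitney U;
#' ordinal scores (`aspects`, `collateral_grade`) use Mann-Whitney;
#' binary/categorical variables use the Pearson chi-square test without
#' continuity correction (Fisher's exact test when any expected cell count
#' is below 5). Variables with `p < alpha` are candidates for the combined
#' model.
#'
#' @param covariates Data.frame of clinical variables (any subset of the
#'   cohort columns; non-covariate columns `id`, `tfs_class`, `split` are
#'   ignored).
#' @param labels TFS labels.
#' @param alpha Significance level (default 0.05).
#' @return Data.frame: `variable`, `test`, `p`, `selected`.
#' @export
screen_clinical <- function(covariates, labels, alpha = 0.05) {
  labels <- as_tfs_label(labels)
  vars <- setdiff(colnames(covariates), c("id", "tfs_class", "split"))
  ordinal <- c("aspects", "collateral_grade")
  res <- lapply(vars, function(v) {
    x <- covariates[[v]]
    if (is.numeric(x) && length(unique(x)) > 2L && !(v %in% ordinal)) {
      r <- route_two_sample(as.numeric(x), labels)
      test <- r$test; p <- r$p
    } else if (v %in% ordinal) {
      p <- if (stats::sd(as.numeric(x)) == 0) 1 else
        suppressWarnings(wilcox.test(as.numeric(x) ~ labels)$p.value)
      test <- "mann-whitney"
    } else {
      tab <- table(factor(x), labels)
      if (length(unique(x)) < 2L) { test <- "degenerate"; p <- 1 }
      else {
        expct <- outer(rowSums(tab), colSums(tab)) / sum(tab)
        if (any(expct < 5)) {
          test <- "fisher"; p <- fisher.test(tab)$p.value
        } else {
          test <- "chi-square"
          p <- chisq.test(tab, correct = FALSE)$p.value
        }
      }
    }
    data.frame(variable = v, test = test, p = p, selected = p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

## Logistic regression with a small ridge penalty by iteratively
## reweighted least squares; used as the separation fallback.
#' @noRd
ridge_logistic <- function(x, y, lambda = 1e-6, maxit = 100L) {
  x <- cbind(`(Intercept)` = 1, as.matrix(x))
  beta <- rep(0, ncol(x))
  pen <- diag(c(0, rep(lambda, ncol(x) - 1L)))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(x, w * x) + pen, crossprod(x, w * z))
    if (max(abs(new - beta)) < 1e-10) { beta <- new; break }
    beta <- new
  }
  setNames(as.numeric(beta), colnames(x))
}

#' Fit the combined logistic model
#'
#' Maximum-likelihood logistic regression of the TFS class on the
#' rad-score and the screened clinical covariates. Perfect or
#' quasi-perfect separation (non-finite or huge coefficients) triggers a
#' documented ridge fallback (penalty 1e-6) and is flagged.
#'
#' @param radscores Numeric rad-score vector.
#' @param covariates Data.frame of screened clinical covariates (may have
#'   zero columns for a radiomics-only model).
#' @param labels TFS labels.
#' @return A list of class `combined_model`: `coefficients`, `glm` (the
#'   fitted [stats::glm] when regular), `separation` flag, `terms`
#'   (covariate names).
#' @export
fit_combined <- function(radscores, covariates, labels) {
  labels <- as_tfs_label(labels)
  covariates <- as.data.frame(covariates)
  df <- if (ncol(covariates)) data.frame(radscore = radscores, covariates)
        else data.frame(radscore = radscores)
  y <- as.integer(labels == "early")
  fit <- suppressWarnings(glm(y ~ ., data = cbind(y = y, df),
                              family = binomial()))
  sep <- !fit$converged || any(!is.finite(coef(fit))) ||
    any(abs(coef(fit)[-1]) > 10) ||
    any(fitted(fit) < 1e-8) || any(fitted(fit) > 1 - 1e-8)
  if (sep) {
    beta <- ridge_logistic(df, y)
    out <- list(coefficients = beta, glm = NULL, separation = TRUE,
                terms = colnames(df))
  } else {
    out <- list(coefficients = coef(fit), glm = fit, separation = FALSE,
                terms = colnames(df))
  }
  class(out) <- "combined_model"
  out
}

#' @noRd
predict_combined <- function(model, radscores, covariates) {
  df <- data.frame(`(Intercept)` = 1, radscore = radscores, covariates,
                   check.names = FALSE)
  x <- as.matrix(df[, names(model$coefficients), drop = FALSE])
  plogis(as.numeric(x %*% model$coefficients))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are grouped into `g` equal-frequency bins of predicted risk
#' (tied predictions stay in one group); the statistic is
#' `sum((O - E)^2 / (E * (1 - E / n_g)))` over groups with `df = g - 2`
#' and an upper-tail chi-square p-value.
#'
#' @param probs Predicted probabilities.
#' @param labels TFS labels (events = early class).
#' @param g Number of risk groups (default 10).
#' @return A list of class `calibration_result`: `statistic`, `df`, `p`,
#'   `groups` (observed/expected table).
#' @export
hosmer_lemeshow <- function(probs, labels, g = 10L) {
  labels <- as_tfs_label(labels)
  y <- as.integer(labels == "early")
  n <- length(y)
  if (n < 2L * g) stop_radonset("need at least 2 subjects per group")
  br <- unique(quantile(probs, probs = seq(0, 1, length.out = g + 1),
                        type = 7))
  grp <- cut(probs, breaks = br, include.lowest = TRUE)
  obs <- tapply(y, grp, sum)
  expd <- tapply(probs, grp, sum)
  ng <- tapply(y, grp, length)
  keep <- !is.na(ng)
  obs <- obs[keep]; expd <- expd[keep]; ng <- ng[keep]
  if (any(expd <= 0 | expd >= ng))
    expd <- pmin(pmax(expd, 1e-10), ng - 1e-10)
  stat <- sum((obs - expd)^2 / (expd * (1 - expd / ng)))
  df <- length(ng) - 2L
  structure(list(statistic = stat, df = df,
                 p = pchisq(stat, df, lower.tail = FALSE),
                 groups = data.frame(n = as.integer(ng), observed = as.integer(obs),
                                     expected = as.numeric(expd))),
            class = "calibration_result")
}

#' Fit the TFS radiomics signature and combined model
#'
#' The main model-fitting entry point. On the development split it runs
#' the full cascade: drop degenerate features and standardize
#' ([standardize_features()]), univariate filter ([univariate_filter()]),
#' Spearman redundancy elimination ([redundancy_filter()]), LASSO logistic
#' selection at the 10-fold cross-validated deviance minimum
#' ([lasso_select()]); builds the rad-score (LASSO coefficients by
#' default, or an unpenalized refit with `refit = TRUE`); screens the
#' clinical covariates ([screen_clinical()]); and fits the combined
#' logistic model ([fit_combined()]). Validation subjects are never used
#' for standardization, selection or coefficient estimation.
#'
#' @param features Feature table with an `id` column (see
#'   [extract_cohort()]).
#' @param cohort Cohort data.frame with `id`, `tfs_class`, `split` and the
#'   clinical covariates.
#' @param alpha Significance level for the univariate and clinical screens.
#' @param rho_max Spearman redundancy threshold.
#' @param n_folds LASSO cross-validation folds.
#' @param refit Refit the rad-score coefficients by unpenalized logistic
#'   regression on the selected features (default FALSE: LASSO
#'   coefficients are used directly).
#' @param seed Fold seed.
#' @return An object of class `radonset`; see [predict.radonset()],
#'   [evaluate_model()].
#' @examples
#' sim <- simulate_signal_table(n = 160, n_informative = 4, n_noise = 16,
#'                              clinical = TRUE, seed = 7)
#' cohort <- data.frame(id = sprintf("S%03d", 1:160),
#'                      tfs_class = as.character(sim$labels),
#'                      sim$covariates, split = "unassigned")
#' cohort$split <- rep(c("development", "validation"), c(112, 48))
#' features <- cbind(id = cohort$id, sim$features)
#' fit <- radonset(features, cohort, seed = 7)
#' print(fit)
#' @export
radonset <- function(features, cohort, alpha = 0.05, rho_max = 0.9,
                     n_folds = 10L, refit = FALSE,
                     seed = .radonset_default_seed) {
  check_flag(refit, "refit")
  if (is.null(features$id) || is.null(cohort$id))
    stop_radonset("'features' and 'cohort' need an 'id' column")
  if (!all(cohort$id %in% features$id))
    stop_radonset("every cohort subject needs a feature row")
  features <- features[match(cohort$id, features$id), , drop = FALSE]
  dev <- cohort$split == "development"
  if (!any(dev)) stop_radonset("cohort has no development subjects")
  labels <- as_tfs_label(cohort$tfs_class)
  fcols <- setdiff(colnames(features), "id")
  ftab <- features[, fcols, drop = FALSE]

  ## cascade on the development split only
  std <- suppressWarnings(standardize_features(ftab[dev, , drop = FALSE]))
  uni <- univariate_filter(std$table, labels[dev], alpha = alpha)
  surv <- redundancy_filter(std$table, uni, rho_max = rho_max)
  las <- lasso_select(std$table[, surv, drop = FALSE], labels[dev],
                      n_folds = n_folds, seed = seed)

  selected <- names(las$coefficients)
  if (refit && length(selected)) {
    y <- as.integer(labels[dev] == "early")
    rf <- suppressWarnings(glm(y ~ ., family = binomial(),
                               data = cbind(y = y,
                                            std$table[, selected, drop = FALSE])))
    radscore_model <- list(intercept = unname(coef(rf)[1]),
                           coefficients = coef(rf)[-1],
                           standardization = std$params, source = "refit")
  } else {
    radscore_model <- list(intercept = las$intercept,
                           coefficients = las$coefficients,
                           standardization = std$params, source = "lasso")
  }
  class(radscore_model) <- "radscore_model"

  scores_dev <- compute_radscore(radscore_model, ftab[dev, , drop = FALSE])
  screening <- screen_clinical(cohort[dev, , drop = FALSE], labels[dev],
                               alpha = alpha)
  clin_vars <- screening$variable[screening$selected]
  clin <- cohort[dev, clin_vars, drop = FALSE]
  clin[] <- lapply(clin, function(x)
    if (is.character(x)) as.numeric(factor(x)) - 1 else as.numeric(x))
  combined <- fit_combined(scores_dev, clin, labels[dev])

  structure(list(radscore_model = radscore_model, combined_model = combined,
                 univariate = uni, redundancy_survivors = surv,
                 lasso = las, screening = screening,
                 clinical_variables = clin_vars,
                 alpha = alpha, rho_max = rho_max, seed = as.integer(seed),
                 n_dev = sum(dev), n_features = length(fcols),
                 call = match.call()),
            class = "radonset")
}

#' Predict from a fitted TFS radiomics model
#'
#' @param object A [radonset()] fit.
#' @param features Raw feature table with `id`.
#' @param cohort Cohort rows matching `features` (needed for the combined
#'   model's clinical covariates).
#' @param type `"radscore"` (signature linear predictor), `"prob"`
#'   (combined-model probability of the early class), `"prob_radiomics"`
#'   (`plogis(radscore)`, the signature-only probability), or `"class"`
#'   (combined-model class at threshold 0.5).
#' @param ... Unused.
#' @return Numeric (or factor, for `"class"`) vector.
#' @export
predict.radonset <- function(object, features, cohort = NULL,
                             type = c("radscore", "prob", "prob_radiomics",
                                      "class"), ...) {
  type <- match.arg(type)
  ftab <- features[, setdiff(colnames(features), "id"), drop = FALSE]
  rs <- compute_radscore(object$radscore_model, ftab)
  if (type == "radscore") return(rs)
  if (type == "prob_radiomics") return(plogis(rs))
  if (is.null(cohort))
    stop_radonset("combined-model predictions need 'cohort' covariates")
  cohort <- cohort[match(features$id, cohort$id), , drop = FALSE]
  clin <- cohort[, object$clinical_variables, drop = FALSE]
  clin[] <- lapply(clin, function(x)
    if (is.character(x)) as.numeric(factor(x)) - 1 else as.numeric(x))
  pr <- predict_combined(object$combined_model, rs, clin)
  if (type == "prob") pr
  else factor(ifelse(pr >= 0.5, "early", "late"), levels = c("late", "early"))
}

#' @export
print.radonset <- function(x, ...) {
  cat("TFS radiomics model (radonset)\n")
  cat(sprintf("  development subjects: %d; input features: %d\n",
              x$n_dev, x$n_features))
  cat(sprintf("  cascade: %d univariate-passed -> %d after redundancy -> %d in signature\n",
              sum(x$univariate$pass), length(x$redundancy_survivors),
              length(x$radscore_model$coefficients)))
  cat(sprintf("  rad-score source: %s; lambda_min = %.5f\n",
              x$radscore_model$source, x$lasso$lambda_min))
  if (length(x$radscore_model$coefficients)) {
    cat("  signature features:\n")
    for (f in names(x$radscore_model$coefficients))
      cat(sprintf("    %-45s %+.4f\n", f, x$radscore_model$coefficients[[f]]))
  }
  cat(sprintf("  combined model: rad-score + {%s}%s\n",
              paste(x$clinical_variables, collapse = ", "),
              if (x$combined_model$separation) " [ridge fallback]" else ""))
  invisible(x)
}

#' @export
summary.radonset <- function(object, ...) {
  out <- list(fit = object,
              screening = object$screening,
              combined_coefficients = object$combined_model$coefficients)
  class(out) <- "summary.radonset"
  out
}

#' @export
print.summary.radonset <- function(x, ...) {
  print(x$fit)
  cat("\nClinical screening:\n")
  print(x$screening, row.names = FALSE)
  cat("\nCombined-model coefficients:\n")
  print(x$combined_coefficients)
  invisible(x)
}

#' @export
coef.radonset <- function(object, model = c("radscore", "combined"), ...) {
  model <- match.arg(model)
  if (model == "radscore")
    c(`(Intercept)` = object$radscore_model$intercept,
      object$radscore_model$coefficients)
  else object$combined_model$coefficients
}
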