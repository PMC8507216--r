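## Discrimination, comparison, reliability and clinical-utility analytics:
## DeLong AUC/CI and paired ROC comparison (via pROC), Youden operating
## points, McNemar on discordant correctness, decision-curve analysis with
## beneficial-range extraction, two-way ICC, and feature-clinical Spearman
## correlations.

#' @noRd
roc_of <- function(scores, labels) {
  labels <- as_tfs_label(labels)
  if (any(table(labels) == 0L)) stop_radonset("both classes must be present")
  pROC::roc(response = labels, predictor = scores,
            levels = c("late", "early"), direction = "<", quiet = TRUE)
}

#' AUC with DeLong variance and confidence interval
#'
#' AUC is the Mann-Whitney estimator (ties count 1/2); the standard error
#' comes from DeLong placement values and the 95% CI is Wald, truncated to
#' `[0, 1]`.
#'
#' @param scores Numeric scores (higher = more early-like).
#' @param labels TFS labels.
#' @return A list of class `roc_result`: `auc`, `se`, `ci` (length 2),
#'   `curve` (data.frame of threshold/sensitivity/specificity sorted by
#'   threshold), `n_pos`, `n_neg`.
#' @export
auc_delong <- function(scores, labels) {
  r <- roc_of(scores, labels)
  auc <- as.numeric(pROC::auc(r))
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  se <- sqrt(v)
  ci <- pmin(pmax(auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  curve <- data.frame(threshold = r$thresholds,
                      sensitivity = r$sensitivities,
                      specificity = r$specificities)
  curve <- curve[order(curve$threshold), ]
  rownames(curve) <- NULL
  structure(list(auc = auc, se = se, ci = ci, curve = curve,
                 n_pos = sum(as_tfs_label(labels) == "early"),
                 n_neg = sum(as_tfs_label(labels) == "late")),
            class = "roc_result")
}

#' Youden-optimal operating point
#'
#' Maximizes `J = sensitivity + specificity - 1` over the ROC thresholds;
#' ties are broken by higher sensitivity, then lower threshold.
#'
#' @param roc A [auc_delong()] result.
#' @return A list of class `operating_point`: `threshold`, `sensitivity`,
#'   `specificity`, `youden`.
#' @export
youden_point <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  cv <- roc$curve
  j <- cv$sensitivity + cv$specificity - 1
  best <- which(j == max(j))
  best <- best[order(-cv$sensitivity[best], cv$threshold[best])][1]
  structure(list(threshold = cv$threshold[best],
                 sensitivity = cv$sensitivity[best],
                 specificity = cv$specificity[best],
                 youden = j[best]),
            class = "operating_point")
}

#' Paired DeLong comparison of two ROC curves
#'
#' Two-sided z-test on the AUC difference of two scores measured on the
#' same subjects, using the paired DeLong covariance. A degenerate
#' (near-zero) variance of the difference yields `p = 1` with a flag.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels TFS labels.
#' @return A list: `p`, `auc_a`, `auc_b`, `degenerate`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  ra <- roc_of(scores_a, labels)
  rb <- roc_of(scores_b, labels)
  va <- suppressWarnings(pROC::var(ra, method = "delong"))
  cv <- suppressWarnings(pROC::cov(ra, rb, method = "delong"))
  vb <- suppressWarnings(pROC::var(rb, method = "delong"))
  vd <- va + vb - 2 * cv
  if (!is.finite(vd) || vd < 1e-12)
    return(list(p = 1, auc_a = as.numeric(pROC::auc(ra)),
                auc_b = as.numeric(pROC::auc(rb)), degenerate = TRUE))
  tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  list(p = tst$p.value, auc_a = as.numeric(pROC::auc(ra)),
       auc_b = as.numeric(pROC::auc(rb)), degenerate = FALSE)
}

#' McNemar comparison of two classifiers
#'
#' Compares paired binary predictions through their discordant
#' correctness: `b` subjects right under A and wrong under B, `c` the
#' reverse. Exact two-sided binomial test when `b + c < 25`, otherwise
#' chi-square with continuity correction. `b + c = 0` gives `p = 1`.
#'
#' @param pred_a,pred_b Predicted classes (same coding as `labels`).
#' @param labels True TFS labels.
#' @return A list: `p`, `b`, `c`, `method`.
#' @export
mcnemar_compare <- function(pred_a, pred_b, labels) {
  labels <- as_tfs_label(labels)
  ok_a <- as_tfs_label(pred_a) == labels
  ok_b <- as_tfs_label(pred_b) == labels
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  if (b + cc == 0L) return(list(p = 1, b = b, c = cc, method = "none"))
  if (b + cc < 25L) {
    p <- binom.test(b, b + cc, 0.5)$p.value
    method <- "exact-binomial"
  } else {
    stat <- (abs(b - cc) - 1)^2 / (b + cc)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square-cc"
  }
  list(p = p, b = b, c = cc, method = method)
}

#' Decision-curve analysis
#'
#' Net benefit across a grid of threshold probabilities `pt`:
#' `NB_model(pt) = TP/n - (FP/n) * pt/(1-pt)` classifying at
#' `prob >= pt`; `NB_all(pt) = pi - (1-pi) * pt/(1-pt)` (treat-all at
#' prevalence `pi`); `NB_none = 0`. The beneficial range is the longest
#' contiguous grid interval where the model's net benefit strictly exceeds
#' both comparators.
#'
#' @param probs Predicted probabilities of the early class.
#' @param labels TFS labels.
#' @param grid_step Threshold grid step on (0, 1) (default 0.01).
#' @return A list of class `dca_result`: `curve` (data.frame `pt`,
#'   `nb_model`, `nb_all`, `nb_none`), `range` (c(lo, hi) or NULL),
#'   `prevalence`.
#' @export
decision_curve <- function(probs, labels, grid_step = 0.01) {
  labels <- as_tfs_label(labels)
  check_number(grid_step, "grid_step", 1e-6, 0.5)
  y <- as.integer(labels == "early")
  n <- length(y)
  prev <- mean(y)
  pt <- seq(grid_step, 1 - grid_step, by = grid_step)
  w <- pt / (1 - pt)
  nb_model <- vapply(seq_along(pt), function(i) {
    cls <- probs >= pt[i]
    sum(cls & y == 1) / n - sum(cls & y == 0) / n * w[i]
  }, numeric(1))
  nb_all <- prev - (1 - prev) * w
  beats <- nb_model > pmax(nb_all, 0)
  rng <- NULL
  if (any(beats)) {
    runs <- rle(beats)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    tr <- which(runs$values)
    best <- tr[which.max(runs$lengths[tr])]
    rng <- round(c(pt[starts[best]], pt[ends[best]]), 2)
  }
  structure(list(curve = data.frame(pt = pt, nb_model = nb_model,
                                    nb_all = nb_all, nb_none = 0),
                 range = rng, prevalence = prev),
            class = "dca_result")
}

#' Intraclass correlation coefficients
#'
#' Two-way ANOVA decomposition of a subjects-by-raters rating matrix.
#' `mode = "inter"` gives ICC(2,1) (two-way random effects, absolute
#' agreement, single measures); `mode = "intra"` gives ICC(3,1) (two-way
#' mixed effects, consistency, single measures). Zero between-subject
#' variance yields 0 with a flag; values are clamped to `[-1, 1]`.
#'
#' @param ratings Numeric matrix, subjects x raters (>= 5 subjects, >= 2
#'   raters).
#' @param mode `"inter"` (ICC(2,1)) or `"intra"` (ICC(3,1)).
#' @return A list: `icc`, `mode`, `degenerate`.
#' @export
icc_agreement <- function(ratings, mode = c("inter", "intra")) {
  mode <- match.arg(mode)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L || k < 2L) stop_radonset("need >= 5 subjects and >= 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)           # between subjects
  ssc <- n * sum((col_m - grand)^2)           # between raters
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < .Machine$double.eps)
    return(list(icc = 0, mode = mode, degenerate = TRUE))
  icc <- if (mode == "inter")
    (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  else
    (msr - mse) / (msr + (k - 1) * mse)
  list(icc = min(max(icc, -1), 1), mode = mode, degenerate = FALSE)
}

#' Per-feature ICC between two feature extractions
#'
#' Convenience wrapper of [icc_agreement()] over the columns of two
#' feature tables (e.g. extractions under rater A's and rater B's masks).
#'
#' @param table_a,table_b Feature tables with identical columns and
#'   matched rows.
#' @param mode Passed to [icc_agreement()].
#' @return A list: `icc` (named vector), `min`, `max`, `median`.
#' @export
icc_features <- function(table_a, table_b, mode = c("inter", "intra")) {
  mode <- match.arg(mode)
  cols <- setdiff(intersect(colnames(table_a), colnames(table_b)), "id")
  vals <- vapply(cols, function(f) {
    icc_agreement(cbind(as.numeric(table_a[[f]]),
                        as.numeric(table_b[[f]])), mode = mode)$icc
  }, numeric(1))
  list(icc = vals, min = min(vals), max = max(vals),
       median = median(vals))
}

#' Spearman correlations between selected features and clinical factors
#'
#' Mid-rank Spearman rho with the t-approximation p-value for every
#' (feature, covariate) pair. Constant columns give `NA` with a warning.
#'
#' @param features Feature table (selected features).
#' @param covariates Numeric clinical covariates (e.g. age, ASPECTS).
#' @return A list of matrices `rho` and `p` (features x covariates).
#' @export
spearman_feature_clinical <- function(features, covariates) {
  fcols <- setdiff(colnames(features), "id")
  ccols <- setdiff(colnames(covariates), c("id", "tfs_class", "split"))
  rho <- p <- matrix(NA_real_, length(fcols), length(ccols),
                     dimnames = list(fcols, ccols))
  n <- nrow(features)
  for (f in fcols) for (cv in ccols) {
    x <- as.numeric(features[[f]]); y <- as.numeric(covariates[[cv]])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning(sprintf("constant column in pair (%s, %s)", f, cv),
              call. = FALSE)
      next
    }
    r <- cor(rank(x), rank(y))
    rho[f, cv] <- r
    p[f, cv] <- if (abs(r) >= 1) 0 else
      2 * pt(abs(r) * sqrt((n - 2) / (1 - r^2)), df = n - 2,
             lower.tail = FALSE)
  }
  list(rho = rho, p = p)
}

#' Evaluate a fitted TFS model on a cohort split
#'
#' Computes rad-score and combined-model predictions on the requested
#' split and assembles the discrimination/comparison/calibration/clinical
#' -utility report: DeLong AUC and CI for both models, Youden operating
#' points, the paired DeLong and McNemar comparisons, Hosmer-Lemeshow
#' calibration, and decision curves with beneficial threshold ranges.
#'
#' @param fit A [radonset()] model.
#' @param features Feature table with `id`.
#' @param cohort Cohort data.frame.
#' @param split Which split to evaluate (`"validation"`, `"development"`,
#'   ...); `NULL` evaluates all rows.
#' @return A list of class `radonset_evaluation`.
#' @export
evaluate_model <- function(fit, features, cohort, split = "validation") {
  stopifnot(inherits(fit, "radonset"))
  if (!is.null(split)) cohort <- cohort[cohort$split %in% split, , drop = FALSE]
  if (!nrow(cohort)) stop_radonset("no subjects in the requested split")
  features <- features[match(cohort$id, features$id), , drop = FALSE]
  labels <- as_tfs_label(cohort$tfs_class)

  rs <- predict(fit, features, type = "radscore")
  pr_rad <- plogis(rs)
  pr_comb <- predict(fit, features, cohort, type = "prob")

  roc_rad <- auc_delong(rs, labels)
  roc_comb <- auc_delong(pr_comb, labels)
  op_rad <- youden_point(roc_rad)
  op_comb <- youden_point(roc_comb)
  pred_rad <- ifelse(rs >= op_rad$threshold, "early", "late")
  pred_comb <- ifelse(pr_comb >= op_comb$threshold, "early", "late")

  structure(list(
    n = nrow(cohort), split = split,
    radscore = rs, prob_combined = pr_comb,
    roc_radiomics = roc_rad, roc_combined = roc_comb,
    youden_radiomics = op_rad, youden_combined = op_comb,
    delong = delong_compare(rs, pr_comb, labels),
    mcnemar = mcnemar_compare(pred_rad, pred_comb, labels),
    hosmer_lemeshow_radiomics =
      if (nrow(cohort) >= 20) hosmer_lemeshow(pr_rad, labels) else NULL,
    hosmer_lemeshow_combined =
      if (nrow(cohort) >= 20) hosmer_lemeshow(pr_comb, labels) else NULL,
    dca_radiomics = decision_curve(pr_rad, labels),
    dca_combined = decision_curve(pr_comb, labels)),
    class = "radonset_evaluation")
}

#' @export
print.radonset_evaluation <- function(x, ...) {
  fmt <- function(r) sprintf("%.3f (95%% CI %.3f-%.3f)", r$auc, r$ci[1], r$ci[2])
  cat(sprintf("TFS model evaluation (%s, n = %d)\n",
              paste(x$split %||% "all", collapse = "+"), x$n))
  cat("  radiomics signature AUC:", fmt(x$roc_radiomics), "\n")
  cat("  combined model AUC:     ", fmt(x$roc_combined), "\n")
  cat(sprintf("  Youden (radiomics): sens %.1f%%, spec %.1f%%\n",
              100 * x$youden_radiomics$sensitivity,
              100 * x$youden_radiomics$specificity))
  cat(sprintf("  Youden (combined):  sens %.1f%%, spec %.1f%%\n",
              100 * x$youden_combined$sensitivity,
              100 * x$youden_combined$specificity))
  cat(sprintf("  DeLong p = %.4f; McNemar p = %.4f\n",
              x$delong$p, x$mcnemar$p))
  if (!is.null(x$hosmer_lemeshow_combined))
    cat(sprintf("  Hosmer-Lemeshow (combined): p = %.3f\n",
                x$hosmer_lemeshow_combined$p))
  rng <- function(d) if (is.null(d$range)) "none"
                     else sprintf("%.2f-%.2f", d$range[1], d$range[2])
  cat(sprintf("  DCA beneficial range: radiomics %s; combined %s\n",
              rng(x$dca_radiomics), rng(x$dca_combined)))
  invisible(x)
}
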