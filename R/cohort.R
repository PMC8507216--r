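## Synthetic cohort generation.
##
## The generator emulates the clinical covariate structure of a two-stratum
## M1-MCAO cohort (time from stroke onset <= 4.5 h, "early", n = 46, versus
## > 4.5 h, "late", n = 77): age as a truncated normal per stratum, ASPECTS
## from an explicit integer probability vector matched to the per-stratum
## median/IQR targets, NIHSS as a discretized log-normal, and risk-factor
## booleans as Bernoulli draws at the per-stratum prevalences.

## ASPECTS probability vectors on 0..10, chosen so that at large n the
## early stratum has median 8 with quartiles near (5.25, 9) and the late
## stratum median 6 with quartiles (3, 9).
.aspects_pmf_early <- c(0.02, 0.02, 0.03, 0.04, 0.05, 0.09, 0.10, 0.12, 0.23, 0.20, 0.10)
.aspects_pmf_late  <- c(0.05, 0.06, 0.07, 0.12, 0.08, 0.08, 0.10, 0.08, 0.10, 0.16, 0.10)

## Collateral grade distribution on 0..3 (median 1, IQR 1-1 in both strata).
.collateral_pmf <- c(0.15, 0.70, 0.10, 0.05)

## Log-normal NIHSS parameters fit to the per-stratum median (IQR):
## meanlog = log(median), sdlog = log(q75/q25) / (2 * qnorm(0.75)).
.nihss_lnorm <- function(median, q25, q75)
  c(meanlog = log(median), sdlog = log(q75 / q25) / (2 * qnorm(0.75)))

#' Specification of a synthetic two-stratum stroke cohort
#'
#' Returns the parameter set from which [generate_cohort()] draws: stratum
#' sizes, per-stratum age mean/SD (years), integer probability vectors for
#' ASPECTS (0--10) and collateral grade (0--3), log-normal parameters for
#' NIHSS, and per-stratum prevalences of the binary covariates. Defaults
#' reproduce the covariate summaries of the study population the generator
#' emulates (46 early / 77 late subjects; early age 75.17 +/- 12.39 years,
#' late 70.12 +/- 12.97; early median ASPECTS 8, late 6; and so on).
#'
#' @param n_early,n_late Stratum sizes (positive integers; default 46 / 77).
#' @param age_mean,age_sd Named-by-position length-2 numeric vectors
#'   `(early, late)` for the age distribution in years. Ages are drawn
#'   truncated-normal on `[18, 100]` with the parent parameters calibrated
#'   so the truncated distribution has exactly this mean and SD.
#' @param prevalence A named list of length-2 numeric vectors `(early, late)`
#'   with Bernoulli prevalences in `[0, 1]` for `male`, `hypertension`,
#'   `diabetes`, `hyperlipidemia`, `atrial_fibrillation`, `smoking`,
#'   `alcohol`, `hvs`, `ica_occlusion` and `right_side`.
#' @param aspects_pmf,collateral_pmf Lists with elements `early`, `late`:
#'   probability vectors over ASPECTS 0..10 and collateral grade 0..3.
#' @param nihss A list with elements `early`, `late`, each `c(meanlog, sdlog)`
#'   of the log-normal NIHSS model (discretized and clamped to 0..42).
#' @param seed Integer master seed.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec()
#' cohort <- generate_cohort(spec)
#' table(cohort$tfs_class)
#' @export
cohort_spec <- function(n_early = 46L, n_late = 77L,
                        age_mean = c(early = 75.17, late = 70.12),
                        age_sd = c(early = 12.39, late = 12.97),
                        prevalence = list(
                          male = c(0.6739, 0.6104),
                          hypertension = c(0.6739, 0.6494),
                          diabetes = c(0.1957, 0.1818),
                          hyperlipidemia = c(0.2609, 0.1948),
                          atrial_fibrillation = c(0.5435, 0.4675),
                          smoking = c(0.3261, 0.3506),
                          alcohol = c(0.2174, 0.2078),
                          hvs = c(0.6087, 0.5065),
                          ica_occlusion = c(0.4130, 0.4156),
                          right_side = c(0.4130, 0.5844)),
                        aspects_pmf = list(early = .aspects_pmf_early,
                                           late = .aspects_pmf_late),
                        collateral_pmf = list(early = .collateral_pmf,
                                              late = .collateral_pmf),
                        nihss = list(early = .nihss_lnorm(19.5, 16, 22.25),
                                     late = .nihss_lnorm(19, 13, 25)),
                        seed = .radonset_default_seed) {
  if (n_early < 0 || n_late < 0 || n_early + n_late <= 0)
    stop_radonset("stratum sizes must be non-negative with at least one subject")
  if (any(age_sd <= 0)) stop_radonset("age SDs must be positive")
  for (nm in names(prevalence)) {
    p <- prevalence[[nm]]
    if (length(p) != 2L || any(p < 0) || any(p > 1))
      stop_radonset(sprintf("prevalence '%s' must be two values in [0, 1]", nm))
  }
  for (pm in c(aspects_pmf, collateral_pmf)) {
    if (any(pm < 0) || abs(sum(pm) - 1) > 1e-8)
      stop_radonset("probability vectors must be non-negative and sum to 1")
  }
  cls2 <- c("early", "late")
  structure(list(n_early = as.integer(n_early), n_late = as.integer(n_late),
                 age_mean = setNames(as.numeric(age_mean), cls2),
                 age_sd = setNames(as.numeric(age_sd), cls2),
                 prevalence = lapply(prevalence, as.numeric),
                 aspects_pmf = setNames(lapply(aspects_pmf, as.numeric), cls2),
                 collateral_pmf = setNames(lapply(collateral_pmf, as.numeric), cls2),
                 nihss = setNames(lapply(nihss, function(v)
                   setNames(as.numeric(v), c("meanlog", "sdlog"))), cls2),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## Truncated-normal draw on [lo, hi] by rejection (vectorized refill).
#' @noRd
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

## Mean and SD of a normal(mu, sigma) truncated to [lo, hi] (closed form).
#' @noRd
truncnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  d1 <- (stats::dnorm(a) - stats::dnorm(b)) / z
  m <- mu + sigma * d1
  v <- sigma^2 * (1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z - d1^2)
  c(mean = m, sd = sqrt(v))
}

## Parent-normal parameters whose [lo, hi]-truncation has the target
## mean/SD, so truncation does not bias the calibrated moments.
#' @noRd
solve_truncnorm_params <- function(target_mean, target_sd, lo, hi) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (mo[1] - target_mean)^2 + (mo[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

#' @noRd
draw_stratum <- function(n, cls, spec) {
  i <- if (cls == "early") 1L else 2L
  nl <- spec$nihss[[cls]]
  ap <- solve_truncnorm_params(spec$age_mean[i], spec$age_sd[i], 18, 100)
  data.frame(
    id = character(n),
    tfs_class = rep(cls, n),
    age = rtruncnorm(n, ap[1], ap[2], 18, 100),
    sex = ifelse(rbinom(n, 1, spec$prevalence$male[i]) == 1, "male", "female"),
    nihss = pmin(42L, pmax(0L, as.integer(round(rlnorm(n, nl[1], nl[2]))))),
    aspects = sample(0:10, n, replace = TRUE, prob = spec$aspects_pmf[[cls]]),
    hypertension = rbinom(n, 1, spec$prevalence$hypertension[i]) == 1,
    diabetes = rbinom(n, 1, spec$prevalence$diabetes[i]) == 1,
    hyperlipidemia = rbinom(n, 1, spec$prevalence$hyperlipidemia[i]) == 1,
    atrial_fibrillation = rbinom(n, 1, spec$prevalence$atrial_fibrillation[i]) == 1,
    smoking = rbinom(n, 1, spec$prevalence$smoking[i]) == 1,
    alcohol = rbinom(n, 1, spec$prevalence$alcohol[i]) == 1,
    hvs = rbinom(n, 1, spec$prevalence$hvs[i]) == 1,
    ica_occlusion = rbinom(n, 1, spec$prevalence$ica_occlusion[i]) == 1,
    collateral_grade = sample(0:3, n, replace = TRUE,
                              prob = spec$collateral_pmf[[cls]]),
    side = ifelse(rbinom(n, 1, spec$prevalence$right_side[i]) == 1,
                  "right", "left"),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws one subject record per row from the per-stratum covariate
#' distributions of `spec`. In `"replica"` mode (default) the cohort holds
#' exactly `n_early` early-window and `n_late` late-window subjects, so
#' composition-anchored checks are deterministic; in `"sample"` mode each
#' subject's class is a Bernoulli draw with prevalence
#' `n_early / (n_early + n_late)`.
#'
#' @param spec A [cohort_spec()].
#' @param mode `"replica"` (fixed stratum sizes) or `"sample"`.
#' @param seed Optional integer seed overriding `spec$seed`.
#' @return A data.frame with one row per subject: `id`, `tfs_class`
#'   (`"early"`/`"late"`), the clinical covariates, and a `split` column
#'   initialized to `"unassigned"` (see [split_cohort()]).
#' @examples
#' cohort <- generate_cohort(cohort_spec())
#' table(cohort$tfs_class)  # 46 early, 77 late
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            mode = c("replica", "sample"),
                            seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  mode <- match.arg(mode)
  seed <- seed %||% spec$seed
  with_seed(seed, {
    if (mode == "replica") {
      n_early <- spec$n_early; n_late <- spec$n_late
    } else {
      n <- spec$n_early + spec$n_late
      n_early <- sum(rbinom(n, 1, spec$n_early / n))
      n_late <- n - n_early
    }
    parts <- list()
    if (n_early > 0) parts <- c(parts, list(draw_stratum(n_early, "early", spec)))
    if (n_late > 0) parts <- c(parts, list(draw_stratum(n_late, "late", spec)))
    cohort <- do.call(rbind, parts)
    cohort$id <- sprintf("S%04d", seq_len(nrow(cohort)))
    cohort$split <- "unassigned"
    rownames(cohort) <- NULL
    validate_cohort(cohort)
    cohort
  })
}

#' @noRd
validate_cohort <- function(cohort) {
  req <- c("id", "tfs_class", "age", "sex", "nihss", "aspects", "hypertension",
           "diabetes", "hyperlipidemia", "atrial_fibrillation", "smoking",
           "alcohol", "hvs", "ica_occlusion", "collateral_grade", "side")
  miss <- setdiff(req, names(cohort))
  if (length(miss))
    stop_radonset("cohort is missing columns: ", paste(miss, collapse = ", "))
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      stop_radonset(sprintf("%s out of range at row(s) %s", what,
                            paste(head(idx, 5), collapse = ", ")))
  }
  bad(!(cohort$aspects %in% 0:10), "ASPECTS")
  bad(!(cohort$nihss %in% 0:42), "NIHSS")
  bad(!(cohort$collateral_grade %in% 0:3), "collateral grade")
  bad(!(cohort$tfs_class %in% c("early", "late")), "TFS class")
  invisible(cohort)
}

#' Assign development/validation split labels
#'
#' Randomly assigns exactly `n_dev` subjects to the development split and
#' `n_val` to the validation split. With `stratify = TRUE` the class
#' proportions in each split match the cohort as closely as integer
#' apportionment allows (largest-remainder rounding of
#' `n_class * n_val / n`).
#'
#' @param cohort A cohort data.frame (rows with `split != "unassigned"` are
#'   left untouched and must not be counted in `n_dev + n_val`).
#' @param n_dev,n_val Split sizes; must sum to the number of unassigned rows.
#' @param stratify Stratify by `tfs_class` (default TRUE).
#' @param seed Integer seed.
#' @return The cohort with its `split` column filled in.
#' @examples
#' cohort <- generate_cohort(cohort_spec())
#' cohort <- split_cohort(cohort, n_dev = 85, n_val = 38, seed = 1)
#' table(cohort$split, cohort$tfs_class)
#' @export
split_cohort <- function(cohort, n_dev, n_val, stratify = TRUE,
                         seed = .radonset_default_seed) {
  if (is.null(cohort$tfs_class) || is.null(cohort$split))
    stop_radonset("cohort needs 'tfs_class' and 'split' columns")
  check_flag(stratify, "stratify")
  idx <- which(cohort$split == "unassigned")
  if (n_dev < 0 || n_val < 0 || n_dev + n_val != length(idx))
    stop_radonset(sprintf(
      "n_dev + n_val (%d) must equal the number of unassigned subjects (%d)",
      n_dev + n_val, length(idx)))
  with_seed(seed, {
    if (stratify) {
      classes <- unique(cohort$tfs_class[idx])
      quota <- vapply(classes, function(cl) sum(cohort$tfs_class[idx] == cl) *
                        n_val / length(idx), numeric(1))
      n_val_cl <- floor(quota)
      rem <- n_val - sum(n_val_cl)
      if (rem > 0) {
        extra <- order(quota - floor(quota), decreasing = TRUE)[seq_len(rem)]
        n_val_cl[extra] <- n_val_cl[extra] + 1
      }
      val_idx <- integer(0)
      for (k in seq_along(classes)) {
        pool <- idx[cohort$tfs_class[idx] == classes[k]]
        val_idx <- c(val_idx, sample(pool, n_val_cl[k]))
      }
    } else {
      val_idx <- sample(idx, n_val)
    }
    cohort$split[idx] <- "development"
    cohort$split[val_idx] <- "validation"
    cohort
  })
}
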