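## Internal helpers shared across modules.

#' Run code under a temporary RNG state
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded package functions do not disturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Master seed used by every stochastic default in the package.
.radonset_default_seed <- 20210123L

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_radonset <- function(...) stop(..., call. = FALSE)

#' @noRd
check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_radonset(sprintf("'%s' must be TRUE or FALSE", name))
  invisible(x)
}

#' @noRd
check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_radonset(sprintf("'%s' must be a finite number in [%s, %s]",
                          name, format(lower), format(upper)))
  invisible(x)
}

#' Normalize a TFS label vector to a factor with levels late < early
#'
#' The positive class throughout the package is `early` (onset-to-imaging
#' within 4.5 h), so model scores and AUCs are oriented toward the
#' thrombolysis-eligible class.
#' @noRd
as_tfs_label <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.logical(labels)) labels <- ifelse(labels, "early", "late")
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stop_radonset("numeric TFS labels must be 0 (late) or 1 (early)")
    labels <- ifelse(labels == 1, "early", "late")
  }
  if (!all(labels %in% c("early", "late")))
    stop_radonset("TFS labels must be 'early' or 'late'")
  factor(labels, levels = c("late", "early"))
}

## md5 digest of an arbitrary R object via canonical serialization to a
## temporary file (used for run manifests).
#' @noRd
object_digest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(x, con, version = 2L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(tf))
}
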