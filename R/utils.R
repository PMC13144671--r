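#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rpois rbinom rbeta rnbinom runif quantile pt
#'   sd var glm binomial coef predict plogis qnorm cor median setNames
#' @importFrom utils head modifyList
#' @importFrom data.table data.table as.data.table rbindlist dcast fread
#'   fwrite := .N .SD
NULL

utils::globalVariables(c("count", "short", "long", "fsr", "bin", "n",
                         "sample_id", "window_id", "class", "length", "."))

#' The eight cancer types handled by the assay, in fixed alphabetical order
#'
#' Class order everywhere in the package is `"healthy"` first, then these
#' eight labels, so serialized models and probability matrices stay aligned.
#'
#' @return Character vector of length 8.
#' @export
cancer_types <- function() {
  c("breast", "colorectal", "gastric", "liver", "lung",
    "ovarian", "pancreatic", "prostate")
}

#' Full class label order (healthy + eight cancer types)
#' @return Character vector of length 9.
#' @export
class_levels <- function() c("healthy", cancer_types())

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded package
#' operations do not disturb the global RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single non-missing number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Rank-based binary ROC AUC
#'
#' Mann-Whitney statistic: probability that a random positive scores above a
#' random negative, with ties counted half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positive Logical vector, `TRUE` for the positive class.
#' @return AUC in \[0, 1\], or `NA` if either class is empty.
#' @export
auc_binary <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  keep <- !is.na(scores) & !is.na(positive)
  scores <- scores[keep]; positive <- as.logical(positive[keep])
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(est, lo, hi)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(est = NA_real_, lo = NA_real_, hi = NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(est = p, lo = max(0, ctr - hw), hi = min(1, ctr + hw))
}

clip01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a
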