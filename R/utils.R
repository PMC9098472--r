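#' Derive a reproducible sub-seed from a base seed and a purpose key
#'
#' Independent RNG streams (baselines, patient effects, detection thresholds,
#' permutations, bootstrap draws, ...) are derived from one base seed plus a
#' character/numeric key so changing one component never perturbs the others.
#' The result is always a non-negative integer below 2^31 - 1.
#'
#' @param base integer base seed.
#' @param ... key components (coerced to character) identifying the stream.
#' @return An integer seed suitable for [set.seed()].
#' @export
#' @examples
#' deriveSeed(1, "thresholds")
#' deriveSeed(1, "bootstrap", 5, 12)
deriveSeed <- function(base, ...) {
  if (length(base) != 1L || is.na(base)) {
    stop("'base' must be a single non-missing number")
  }
  M <- 2147483647
  h <- 0
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "/")
  if (nzchar(key)) {
    for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% M
  }
  b <- as.numeric(base) %% M
  if (b < 0) b <- b + M
  as.integer((b * 48271 + h) %% M)
}

# Moment-form (bias-uncorrected) skewness / excess kurtosis live in e1071
# (type = 1); thin wrappers keep the estimator choice in one place.
momentSkewness <- function(x) e1071::skewness(x, na.rm = TRUE, type = 1)
momentKurtosis <- function(x) e1071::kurtosis(x, na.rm = TRUE, type = 1)

#' @importFrom methods is new validObject slot
#' @importFrom stats approx median p.adjust plogis pnorm pt quantile rbinom
#'   rnorm runif sd var wilcox.test setNames rchisq mad cor
#' @importFrom utils combn read.delim write.table
NULL
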