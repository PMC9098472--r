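#' BootstrapDesign: the bootstrap experimental design
#'
#' @slot sizes inclusive integer range of per-group sizes (default 3..23).
#' @slot replicates bootstrap datasets per size (default 100).
#' @slot baseSeed integer base seed.
#' @slot pair the two compared conditions (reference first).
#' @exportClass BootstrapDesign
setClass("BootstrapDesign",
  representation(sizes = "integer", replicates = "integer",
                 baseSeed = "numeric", pair = "character"))

setValidity("BootstrapDesign", function(object) {
  msg <- character(0)
  if (length(object@sizes) < 1L) msg <- c(msg, "empty size range")
  if (any(object@sizes < 2L)) msg <- c(msg, "minimum group size is 2")
  if (object@replicates < 1L) msg <- c(msg, "replicates must be >= 1")
  if (length(object@pair) != 2L) msg <- c(msg, "pair must name two conditions")
  if (length(msg)) msg else TRUE
})

#' Construct a bootstrap design
#'
#' @param sizes integer vector of group sizes (default `3:23`).
#' @param replicates bootstrap datasets per size (default 100).
#' @param baseSeed integer base seed.
#' @param pair compared conditions, reference first (default
#'   `c("r1:25", "r1:12")`).
#' @return A [BootstrapDesign-class].
#' @export
#' @examples
#' enumerateDesign(bootstrapDesign(sizes = 3:5, replicates = 2))
bootstrapDesign <- function(sizes = 3:23, replicates = 100, baseSeed = 1,
                            pair = c("r1:25", "r1:12")) {
  new("BootstrapDesign", sizes = as.integer(sizes),
      replicates = as.integer(replicates), baseSeed = baseSeed,
      pair = as.character(pair))
}

setMethod("show", "BootstrapDesign", function(object) {
  cat(sprintf("BootstrapDesign: sizes %d..%d x %d replicates = %d datasets, pair %s vs %s\n",
              min(object@sizes), max(object@sizes), object@replicates,
              length(object@sizes) * object@replicates,
              object@pair[1], object@pair[2]))
})

#' Enumerate the bootstrap design
#'
#' One entry per (group size, replicate); the per-entry seed is a
#' deterministic function of (base seed, n, replicate) via [deriveSeed()].
#'
#' @param design a [BootstrapDesign-class].
#' @return A `data.frame` with columns `n`, `replicate`, `seed`.
#' @export
enumerateDesign <- function(design) {
  validObject(design)
  grid <- expand.grid(replicate = seq_len(design@replicates),
                      n = design@sizes)[, c("n", "replicate")]
  grid$seed <- mapply(function(n, r) deriveSeed(design@baseSeed, "bootstrap", n, r),
                      grid$n, grid$replicate)
  rownames(grid) <- NULL
  grid
}

#' Draw one bootstrap dataset from two conditions
#'
#' Draws `n` samples independently, uniformly and with replacement from each
#' of the two compared conditions and materializes them as a two-group matrix
#' in which duplicated samples appear as duplicated columns (standard
#' bootstrap semantics). Bit-reproducible for a fixed seed.
#'
#' @param x a [SpikeInExperiment-class].
#' @param n per-group size.
#' @param seed integer seed for this draw.
#' @param pair the two condition labels (reference first).
#' @return A list with `matrix` (columns renamed uniquely), `groups`
#'   (two-level factor, reference level first), `drawn` (named list of drawn
#'   sample ids per condition), `n`, `seed`.
#' @export
drawBootstrap <- function(x, n, seed, pair = c("r1:25", "r1:12")) {
  cond <- sampleConditions(x)
  absent <- setdiff(pair, cond)
  if (length(absent)) {
    stop(sprintf("condition(s) absent from dataset: %s",
                 paste(absent, collapse = ", ")))
  }
  set.seed(as.integer(seed))
  drawn <- lapply(pair, function(cd) {
    ids <- names(cond)[cond == cd]
    ids[sample.int(length(ids), n, replace = TRUE)]
  })
  names(drawn) <- pair
  cols <- unlist(drawn, use.names = FALSE)
  m <- intensities(x)[, cols, drop = FALSE]
  colnames(m) <- sprintf("%s.b%02d", cols, seq_along(cols))
  groups <- factor(rep(pair, each = n), levels = pair)
  list(matrix = m, groups = groups, drawn = drawn, n = n, seed = seed)
}

#' Compute data characteristics of a two-group bootstrap matrix
#'
#' Moment statistics on the observed log2 values: per-group sample variance
#' (n-1 denominator), skewness and excess kurtosis in the bias-uncorrected
#' moment form, the between-group variance ratio (group-2 median protein
#' variance over group-1), the missing-value fraction, and the median
#' per-protein variance.
#'
#' @param mat two-group matrix (`NA` = missing).
#' @param groups two-level factor of length `ncol(mat)`.
#' @return A one-row `data.frame`; fields that cannot be computed (a group
#'   with fewer than two observed values overall) are `NA` with
#'   `characteristics_ok = FALSE`.
#' @export
dataCharacteristics <- function(mat, groups) {
  gi <- .asGroupIndicator(groups)
  g2 <- gi$g2
  x1 <- mat[, !g2, drop = FALSE]
  x2 <- mat[, g2, drop = FALSE]
  obs1 <- x1[!is.na(x1)]
  obs2 <- x2[!is.na(x2)]
  ok <- length(obs1) >= 2 && length(obs2) >= 2
  st <- .groupStats(mat, g2)
  medVar1 <- median(st$v1, na.rm = TRUE)
  medVar2 <- median(st$v2, na.rm = TRUE)
  data.frame(
    var_group1 = if (ok) var(obs1) else NA_real_,
    var_group2 = if (ok) var(obs2) else NA_real_,
    skewness = if (ok) momentSkewness(c(obs1, obs2)) else NA_real_,
    kurtosis = if (ok) momentKurtosis(c(obs1, obs2)) else NA_real_,
    variance_ratio = if (ok && is.finite(medVar1) && medVar1 > 0)
      medVar2 / medVar1 else NA_real_,
    missing_fraction = mean(is.na(mat)),
    median_protein_variance = median(c(st$v1, st$v2), na.rm = TRUE),
    characteristics_ok = ok)
}
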