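#' Sparsity reduction: protein-wise filtering by observed fraction
#'
#' `NoSR` keeps everything; `SR66` / `SR90` keep a protein iff its fraction of
#' observed cells over all samples is at least 0.66 / 0.90 (set
#' `strict = TRUE` for a strict inequality). Removed protein ids are recorded
#' so evaluation can coerce their p-values to 1.
#'
#' @param x a proteins x samples matrix (`NA` = missing) or a
#'   [SpikeInExperiment-class].
#' @param level one of `"NoSR"`, `"SR66"`, `"SR90"`.
#' @param strict use `>` instead of `>=` at the threshold.
#' @return For matrices, a list with `matrix` and `removed` (character ids);
#'   for `SpikeInExperiment`, the filtered object with the removed ids in
#'   `metadata(x)$removedBySR`.
#' @export
setGeneric("sparsityReduce",
           function(x, level = c("NoSR", "SR66", "SR90"), strict = FALSE)
             standardGeneric("sparsityReduce"))

.srKeep <- function(m, level, strict) {
  level <- match.arg(level, c("NoSR", "SR66", "SR90"))
  if (level == "NoSR") return(rep(TRUE, nrow(m)))
  thr <- if (level == "SR66") 0.66 else 0.90
  frac <- rowMeans(!is.na(m))
  if (strict) frac > thr else frac >= thr
}

#' @rdname sparsityReduce
#' @export
setMethod("sparsityReduce", "matrix", function(x, level, strict = FALSE) {
  keep <- .srKeep(x, level, strict)
  list(matrix = x[keep, , drop = FALSE], removed = rownames(x)[!keep])
})

#' @rdname sparsityReduce
#' @export
setMethod("sparsityReduce", "SpikeInExperiment", function(x, level,
                                                          strict = FALSE) {
  keep <- .srKeep(intensities(x), level, strict)
  out <- x[keep, ]
  md <- metadata(out)
  md$removedBySR <- rownames(x)[!keep]
  metadata(out) <- md
  out
})

# reference quantile function: across-sample mean of the per-sample empirical
# quantile functions (mid-rank levels, linear interpolation, clamped tails)
.referenceQuantile <- function(valueList) {
  function(p) {
    qs <- vapply(valueList, function(v) {
      m <- length(v)
      if (m == 1L) return(rep(v, length(p)))
      approx(x = (seq_len(m) - 0.5) / m, y = sort(v), xout = p,
             rule = 2)$y
    }, numeric(length(p)))
    if (length(p) == 1L) mean(qs) else rowMeans(as.matrix(qs))
  }
}

.qnMap <- function(values, refQ) {
  # mid-rank quantile levels with average ranks for ties
  m <- length(values)
  lev <- (rank(values, ties.method = "average") - 0.5) / m
  refQ(lev)
}

.normalizeMatrix <- function(m, method, q = 0.5) {
  if (nrow(m) == 0L || ncol(m) == 0L) return(m)
  obs <- lapply(seq_len(ncol(m)), function(j) m[!is.na(m[, j]), j])
  nObs <- vapply(obs, length, integer(1))
  if (any(nObs == 0)) {
    stop(sprintf("sample(s) with zero observed values: %s",
                 paste(colnames(m)[nObs == 0], collapse = ", ")))
  }
  out <- m
  if (method == "unnormalized") return(out)
  if (method == "median") {
    med <- vapply(obs, median, numeric(1))
    grand <- median(med)
    out <- sweep(m, 2, grand - med, "+")
    return(out)
  }
  if (method == "QN") {
    refQ <- .referenceQuantile(obs)
    for (j in seq_len(ncol(m))) {
      idx <- !is.na(m[, j])
      out[idx, j] <- .qnMap(m[idx, j], refQ)
    }
    return(out)
  }
  # TRQN: quantile-normalize only the top q fraction of each sample; shift the
  # MNAR-contaminated lower tail by the offset the mapping applies at the
  # per-sample q-th quantile boundary (continuous, monotone)
  topList <- lapply(obs, function(v) {
    k <- max(1L, ceiling(q * length(v)))
    sort(v, decreasing = TRUE)[seq_len(k)]
  })
  refQ <- .referenceQuantile(topList)
  for (j in seq_len(ncol(m))) {
    idx <- which(!is.na(m[, j]))
    v <- m[idx, j]
    k <- max(1L, ceiling(q * length(v)))
    cutoff <- sort(v, decreasing = TRUE)[k]   # per-sample q-th quantile
    top <- v >= cutoff
    mappedTop <- .qnMap(v[top], refQ)
    offset <- mappedTop[which.min(v[top])] - min(v[top])
    res <- v
    res[top] <- mappedTop
    res[!top] <- v[!top] + offset
    out[idx, j] <- res
  }
  out
}

#' Normalize a log2 intensity dataset
#'
#' Methods: `unnormalized` (identity); `median` (each sample shifted so its
#' observed median equals the grand median of the pre-normalization sample
#' medians, preserving the absolute intensity scale); `QN` (each observed
#' value replaced by the reference quantile at its mid-rank level, where the
#' reference quantile function is the across-sample mean of the per-sample
#' empirical quantile functions); `TRQN` (QN built from only the top `q`
#' fraction of each sample's observed values — robust against an
#' MNAR-truncated lower tail — with values below the per-sample boundary
#' shifted by the boundary offset). Missing cells stay missing; all methods
#' are monotone within each sample.
#'
#' @param x matrix (`NA` = missing) or [SpikeInExperiment-class] on the log2
#'   scale.
#' @param method one of `"unnormalized"`, `"median"`, `"QN"`, `"TRQN"`.
#' @param q TRQN tail fraction in (0, 1\]; `q = 1` on complete data equals QN.
#' @return Object of the same type as `x`.
#' @export
setGeneric("normalizeIntensities",
           function(x, method = c("unnormalized", "median", "QN", "TRQN"),
                    q = 0.5) standardGeneric("normalizeIntensities"))

#' @rdname normalizeIntensities
#' @export
setMethod("normalizeIntensities", "matrix", function(x, method, q = 0.5) {
  method <- match.arg(method, c("unnormalized", "median", "QN", "TRQN"))
  if (q <= 0 || q > 1) stop("TRQN tail fraction q must be in (0, 1]")
  .normalizeMatrix(x, method, q)
})

#' @rdname normalizeIntensities
#' @export
setMethod("normalizeIntensities", "SpikeInExperiment",
          function(x, method, q = 0.5) {
  method <- match.arg(method, c("unnormalized", "median", "QN", "TRQN"))
  if (q <= 0 || q > 1) stop("TRQN tail fraction q must be in (0, 1]")
  assay(x, "log2intensity") <- .normalizeMatrix(intensities(x), method, q)
  x
})
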