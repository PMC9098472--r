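#' SamParams / RotsParams are plain arguments of [samTest()] and [rotsTest()];
#' both tests share the group-preserving permutation machinery below.
#'
#' @noRd
NULL

# all (or nPerm random) group-size-preserving label assignments, as a logical
# matrix (samples x permutations) of group-2 membership; when the number of
# distinct assignments is <= nPerm they are enumerated exactly
.permutationSet <- function(g2, nPerm) {
  n <- length(g2)
  n2 <- sum(g2)
  nDistinct <- choose(n, n2)
  if (nDistinct < 2) stop("fewer than 2 distinct permutations possible")
  if (nDistinct <= nPerm) {
    idx <- combn(n, n2)
    P <- matrix(FALSE, n, ncol(idx))
    P[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n2))] <- TRUE
    list(P = P, exact = TRUE)
  } else {
    P <- vapply(seq_len(nPerm), function(b) g2[sample.int(n)], logical(n))
    list(P = P, exact = FALSE)
  }
}

# Tusher pooled standard error: s = sqrt((1/n1 + 1/n2) * pooled variance)
.samS <- function(st) {
  pooled <- ((st$n1 - 1) * st$v1 + (st$n2 - 1) * st$v2) / (st$n1 + st$n2 - 2)
  sqrt((1 / st$n1 + 1 / st$n2) * pooled)
}

# fudge-factor selection: s0 from the percentile grid of s minimizing the
# coefficient of variation of the MADs of d across quantile bins of s
.samS0 <- function(m2m1, s, grid = seq(0, 1, by = 0.05), nBins = 10L) {
  ok <- is.finite(s)
  if (!any(ok)) return(0)
  cand <- unique(quantile(s[ok], probs = grid, names = FALSE))
  breaks <- unique(quantile(s[ok], probs = seq(0, 1, length.out = nBins + 1),
                            names = FALSE))
  if (length(breaks) < 2) return(cand[1])
  bins <- cut(s[ok], breaks = breaks, include.lowest = TRUE)
  cv <- vapply(cand, function(s0) {
    d <- m2m1[ok] / (s[ok] + s0)
    mads <- tapply(d, bins, mad)
    mads <- mads[is.finite(mads)]
    mu <- mean(mads)
    if (!length(mads) || !is.finite(mu) || mu == 0) return(Inf)
    sd(mads) / mu
  }, numeric(1))
  if (all(!is.finite(cv))) return(cand[1])
  cand[which.min(cv)]
}

# pooled-null permutation p-values: count of |null| >= |obs| over all
# permutations and all genes, divided by (nPerm * nGenes)
.pooledPermutationP <- function(obsAbs, nullAbs, nPerm, nGenes) {
  pooled <- sort(nullAbs[is.finite(nullAbs)])
  nBelow <- findInterval(obsAbs, pooled, left.open = TRUE)
  (length(pooled) - nBelow) / (nPerm * nGenes)
}

#' Significance analysis of microarrays (SAM) permutation test
#'
#' Per-gene statistic `d = (mean2 - mean1) / (s + s0)` with `s` the pooled
#' two-sample standard error and the fudge factor `s0` chosen from the
#' percentile grid (0, 5, ..., 100) of the gene-wise standard errors to
#' minimize the coefficient of variation of the median absolute deviation of
#' `d` across standard-error bins. Per-gene p-values use the pooled
#' permutation convention: the count, over all group-preserving label
#' permutations and all genes, of `|d*| >= |d|`, divided by
#' `nPerm * nGenes`. When the number of distinct assignments is at most
#' `nPerm` all of them are enumerated exactly.
#'
#' @param mat proteins x samples log2 matrix; rows need >= 2 observed values
#'   per group to be tested.
#' @param groups two-level factor of length `ncol(mat)`.
#' @param nPerm number of permutations (default 250).
#' @param s0 optional fixed fudge factor overriding the automatic selection.
#' @param seed integer seed for the permutation draws.
#' @return A `data.frame` with `protein`, `p_value`, `log2fc`, `statistic`,
#'   `s0`, `status`.
#' @export
samTest <- function(mat, groups, nPerm = 250, s0 = NULL, seed = 1L) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  gi <- .asGroupIndicator(groups)
  g2 <- gi$g2
  st <- .groupStats(mat, g2)
  testable <- st$n1 >= 2 & st$n2 >= 2
  s <- .samS(st)
  diff <- st$m2 - st$m1
  if (is.null(s0)) s0 <- .samS0(diff[testable], s[testable])

  d <- rep(NA_real_, nrow(mat))
  d[testable] <- diff[testable] / (s[testable] + s0)
  d[testable][!is.finite(d[testable])] <- 0   # zero spread, zero difference

  set.seed(deriveSeed(seed, "sam"))
  perms <- .permutationSet(g2, nPerm)
  nPermUsed <- ncol(perms$P)
  nGenes <- sum(testable)
  sub <- mat[testable, , drop = FALSE]
  nullAbs <- vapply(seq_len(nPermUsed), function(b) {
    stb <- .groupStats(sub, perms$P[, b])
    ok <- stb$n1 >= 2 & stb$n2 >= 2
    db <- (stb$m2 - stb$m1) / (.samS(stb) + s0)
    db[!ok | !is.finite(db)] <- NA_real_
    abs(db)
  }, numeric(nGenes))

  p <- rep(NA_real_, nrow(mat))
  p[testable] <- .pooledPermutationP(abs(d[testable]), nullAbs,
                                     nPermUsed, nGenes)
  data.frame(
    protein = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    p_value = p, log2fc = diff, statistic = d, s0 = s0,
    status = ifelse(testable, "tested", "insufficient_data"),
    row.names = NULL, stringsAsFactors = FALSE)
}
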