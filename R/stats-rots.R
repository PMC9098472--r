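# descending-rank positions of a statistic vector (ties broken stably,
# non-finite pushed last)
.rankPositions <- function(d) {
  d[!is.finite(d)] <- -Inf
  pos <- integer(length(d))
  pos[order(d, decreasing = TRUE)] <- seq_along(d)
  pos
}

# top-list overlap proportion for every list size k = 1..K between two
# rankings: gene g is inside both top-k lists iff max(posA, posB) <= k
.overlapCurve <- function(posA, posB, K) {
  m <- pmax(posA, posB)
  cumsum(tabulate(m[m <= K], nbins = K)) / seq_len(K)
}

# d(alpha1, alpha2) = |m2 - m1| / (alpha1 + alpha2 * s) for every candidate
# (rows of `alphas`), from precomputed group stats
.rotsStatistics <- function(st, alphas) {
  diffAbs <- abs(st$m2 - st$m1)
  s <- .samS(st)
  apply(alphas, 1L, function(a) {
    d <- diffAbs / (a[1] + a[2] * s)
    d[!is.finite(d)] <- 0
    d
  })
}

.rotsCandidates <- function(s) {
  s <- s[is.finite(s) & s > 0]
  if (!length(s)) return(rbind(c(0, 1), c(1, 0)))
  qs <- quantile(s, c(0.01, 0.99), names = FALSE)
  qs <- pmax(qs, 1e-6)
  aGrid <- exp(seq(log(qs[1]), log(qs[2]), length.out = 8))
  rbind(c(0, 1), c(1, 0), cbind(aGrid, 1))
}

#' Reproducibility-optimized test statistic (ROTS)
#'
#' The statistic family `d(a1, a2) = |mean2 - mean1| / (a1 + a2 * s)` spans
#' the ordinary t (`(0, 1)`), the plain mean difference (`(1, 0)`) and
#' intermediate fudge-factor statistics (`(a, 1)` for `a` on a log-spaced grid
#' over percentiles of the gene-wise standard errors `s`). For each candidate
#' and each top-list size `k <= K`, reproducibility is the average overlap
#' proportion of top-k gene lists across `B` pairs of group-preserving
#' bootstrap resamples; it is compared against permuted-label resamples and
#' standardized by the bootstrap spread of the observed overlaps
#' (`Z = (R - R0) / sd(R)`, the reference formulation), and the `(alpha, k)`
#' maximizing `Z` is selected. A candidate whose ranking is perfectly
#' reproducible (`sd(R) = 0`) with positive signal gets `Z = Inf`.
#' Per-gene p-values come from the pooled permutation null of the selected
#' statistic, as in [samTest()].
#'
#' @param mat proteins x samples log2 matrix; rows need >= 2 observed values
#'   per group to be tested.
#' @param groups two-level factor of length `ncol(mat)`.
#' @param B number of bootstrap / permutation resamplings (default 100).
#' @param K largest top-list size considered (default 500, capped at the
#'   number of testable genes).
#' @param candidates optional 2-column matrix of `(a1, a2)` candidates
#'   overriding the default set.
#' @param seed integer seed.
#' @return A `data.frame` with `protein`, `p_value`, `log2fc`, `statistic`,
#'   `status`, plus the selected `alpha1`, `alpha2`, `k` as attributes
#'   `"alpha"` and `"k"`.
#' @export
rotsTest <- function(mat, groups, B = 100, K = 500, candidates = NULL,
                     seed = 1L) {
  if (B < 2) stop("B must be >= 2")
  if (K < 1) stop("K must be >= 1")
  gi <- .asGroupIndicator(groups)
  g2 <- gi$g2
  st <- .groupStats(mat, g2)
  testable <- st$n1 >= 2 & st$n2 >= 2
  diff <- st$m2 - st$m1
  sub <- mat[testable, , drop = FALSE]
  G <- nrow(sub)
  if (G < 2) stop("need >= 2 testable genes")
  K <- min(K, G)

  stSub <- .groupStats(sub, g2)
  if (is.null(candidates)) candidates <- .rotsCandidates(.samS(stSub))
  candidates <- matrix(candidates, ncol = 2)
  nCand <- nrow(candidates)

  set.seed(deriveSeed(seed, "rots"))

  bootPair <- function(z) {
    # group-preserving bootstrap: resample columns within each group of z
    take <- unlist(lapply(split(seq_along(z), z),
                          function(ix) ix[sample.int(length(ix),
                                                     replace = TRUE)]),
                   use.names = FALSE)
    take
  }

  Robs <- array(NA_real_, dim = c(B, nCand, K))
  R0 <- array(NA_real_, dim = c(B, nCand, K))
  for (b in seq_len(B)) {
    i1 <- bootPair(g2); i2 <- bootPair(g2)
    dA <- .rotsStatistics(.groupStats(sub[, i1, drop = FALSE], g2[i1]),
                          candidates)
    dB <- .rotsStatistics(.groupStats(sub[, i2, drop = FALSE], g2[i2]),
                          candidates)
    # null pair: labels shuffled independently for each member, so that no
    # shared structure survives in the randomized reference
    zp1 <- g2[sample.int(length(g2))]
    zp2 <- g2[sample.int(length(g2))]
    j1 <- bootPair(zp1); j2 <- bootPair(zp2)
    nA <- .rotsStatistics(.groupStats(sub[, j1, drop = FALSE], zp1[j1]),
                          candidates)
    nB <- .rotsStatistics(.groupStats(sub[, j2, drop = FALSE], zp2[j2]),
                          candidates)
    for (cc in seq_len(nCand)) {
      Robs[b, cc, ] <-
        .overlapCurve(.rankPositions(dA[, cc]), .rankPositions(dB[, cc]), K)
      R0[b, cc, ] <-
        .overlapCurve(.rankPositions(nA[, cc]), .rankPositions(nB[, cc]), K)
    }
  }
  Rbar <- apply(Robs, c(2, 3), mean)
  Rsd <- apply(Robs, c(2, 3), sd)
  R0bar <- apply(R0, c(2, 3), mean)
  num <- Rbar - R0bar
  Z <- num / Rsd
  Z[Rsd == 0 & num > 0] <- Inf
  Z[Rsd == 0 & num <= 0] <- -Inf
  Z[is.na(Z)] <- -Inf
  best <- arrayInd(which.max(Z), dim(Z))
  alphaSel <- candidates[best[1], ]
  kSel <- best[2]

  # pooled permutation null of the selected statistic
  dObs <- .rotsStatistics(stSub, matrix(alphaSel, ncol = 2))[, 1]
  nullAbs <- vapply(seq_len(B), function(b) {
    zp <- g2[sample.int(length(g2))]
    stp <- .groupStats(sub, zp)
    ok <- stp$n1 >= 2 & stp$n2 >= 2
    dp <- .rotsStatistics(stp, matrix(alphaSel, ncol = 2))[, 1]
    dp[!ok] <- NA_real_
    dp
  }, numeric(G))
  pSub <- .pooledPermutationP(dObs, nullAbs, B, G)

  p <- rep(NA_real_, nrow(mat))
  p[testable] <- pSub
  stat <- rep(NA_real_, nrow(mat))
  stat[testable] <- dObs
  out <- data.frame(
    protein = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    p_value = p, log2fc = diff, statistic = stat,
    status = ifelse(testable, "tested", "insufficient_data"),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "alpha") <- alphaSel
  attr(out, "k") <- kSel
  out
}
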