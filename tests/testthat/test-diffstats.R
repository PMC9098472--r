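test_that("log2FC estimation follows the group-mean contract", {
  m <- rbind(P1 = c(20, 20, 21.11, 21.11),
             P2 = c(19, 21, 19, 21),
             P3 = c(NA, NA, 20, 21))
  g <- twoGroups(2)
  fc <- estimateLog2FC(m, g)
  expect_equal(unname(fc), c(1.11, 0, NA))
  out <- runTest(m, g, "t_equal")
  expect_identical(out$status, c("tested", "tested", "insufficient_data"))
  expect_true(is.na(out$p_value[3]))
})

test_that("t tests match stats::t.test and reduce to each other at equal variance", {
  m <- tinyMatrix(40, 12, seed = 3, naFrac = 0.1)
  g <- twoGroups(6)
  oE <- runTest(m, g, "t_equal")
  oW <- runTest(m, g, "t_welch")
  refE <- apply(m, 1, function(x)
    t.test(x[7:12], x[1:6], var.equal = TRUE)$p.value)
  refW <- apply(m, 1, function(x) t.test(x[7:12], x[1:6])$p.value)
  expect_equal(oE$p_value, unname(refE), tolerance = 1e-12)
  expect_equal(oW$p_value, unname(refW), tolerance = 1e-12)

  # identical groups: t statistic 0, p = 1
  ident <- rbind(P1 = c(10, 11, 12, 10, 11, 12))
  expect_equal(runTest(ident, twoGroups(3), "t_equal")$p_value, 1)

  # equal group sizes and equal sample variances: Satterthwaite = pooled
  m2 <- rbind(P1 = c(1, 2, 3, 11, 12, 13), P2 = c(5, 7, 9, 2, 4, 6))
  pE <- runTest(m2, twoGroups(3), "t_equal")$p_value
  pW <- runTest(m2, twoGroups(3), "t_welch")$p_value
  expect_equal(pE, pW, tolerance = 1e-12)
})

test_that("degenerate zero-variance equal-mean input yields p = 1", {
  flat <- rbind(P1 = rep(7, 8))
  for (mm in c("t_equal", "t_welch", "glm_gamma")) {
    expect_equal(runTest(flat, twoGroups(4), mm)$p_value, 1, label = mm)
  }
})

test_that("wilcoxon uses exact enumeration at small n and the tie-corrected approximation", {
  g <- twoGroups(3)
  expect_equal(runTest(rbind(P = 1:6), g, "wilcoxon")$p_value, 0.1)
  # matches wilcox.test with ties / larger n (normal approximation)
  m <- tinyMatrix(25, 20, seed = 9)
  m[1, ] <- round(m[1, ])  # force ties
  g10 <- twoGroups(10)
  o <- runTest(m, g10, "wilcoxon")
  ref <- apply(m, 1, function(x)
    suppressWarnings(wilcox.test(x[11:20], x[1:10], exact = FALSE,
                                 correct = TRUE)$p.value))
  expect_equal(o$p_value, unname(ref), tolerance = 1e-12)
})

test_that("the Gamma GLM closed form matches stats::glm and the log-link identity", {
  m <- tinyMatrix(30, 12, seed = 5, naFrac = 0.1)
  g <- twoGroups(6)
  o <- runTest(m, g, "glm_gamma")
  ref <- apply(m, 1, function(x) {
    d <- data.frame(y = 2^x, grp = factor(rep(c("a", "b"), each = 6)))
    d <- d[!is.na(d$y), ]
    summary(glm(y ~ grp, data = d,
                family = Gamma(link = "log")))$coefficients[2, 4]
  })
  expect_equal(o$p_value, unname(ref), tolerance = 1e-6)

  # noiseless multiplicative shift: coefficient is exactly 1.11 * ln 2
  x1 <- c(18, 19, 20, 21)
  mm <- rbind(P1 = c(x1, x1 + 1.11))
  coef <- spikeBench:::.rowGammaGLM(mm, rep(c(FALSE, TRUE), each = 4))$coef
  expect_equal(coef, 1.11 * log(2), tolerance = 1e-8)
})

test_that("the variance prior fit matches limma and handles the degenerate limit", {
  # cross-check against the independent limma implementation
  set.seed(4)
  mm <- matrix(rnorm(3000 * 8, 0, rep(sqrt(0.25 * 4 / rchisq(3000, 4)), 8)),
               3000, 8)
  g <- rep(c("a", "b"), each = 4)
  s2 <- apply(mm, 1, function(x) (var(x[1:4]) + var(x[5:8])) / 2)
  fit <- limma::fitFDist(s2, df1 = 6)
  prior <- fitVariancePrior(s2, 6)
  expect_equal(prior@d0, fit$df2, tolerance = 1e-6)
  expect_equal(prior@v0, fit$scale, tolerance = 1e-6)
  mt <- moderatedTTest(mm, g)
  eb <- limma::eBayes(limma::lmFit(mm, stats::model.matrix(~factor(g))))
  expect_equal(mt$p_value, unname(eb$p.value[, 2]), tolerance = 1e-9)

  # equal variances: d0 = Inf, moderated t = ordinary t with v0 plugged in
  vEq <- rep(0.5, 50)
  prEq <- fitVariancePrior(vEq, 6)
  expect_identical(prEq@d0, Inf)
  # geometric-mean-based location: the unbiased back-transform of mean(log s^2)
  expect_equal(prEq@v0, 0.5 * exp(log(3) - digamma(3)), tolerance = 1e-12)
  m2 <- tinyMatrix(10, 8, seed = 2)
  mtInf <- moderatedTTest(m2, twoGroups(4), prior = prEq)
  z <- (rowMeans(m2[, 5:8]) - rowMeans(m2[, 1:4])) /
    sqrt(prEq@v0 * (1/4 + 1/4))
  expect_equal(mtInf$p_value, unname(2 * pnorm(abs(z), lower.tail = FALSE)),
               tolerance = 1e-12)
  expect_error(fitVariancePrior(rep(0, 10), 6), "positive")
})

test_that("SAM at n = 3 vs 3 enumerates all 20 assignments exactly", {
  set.seed(5)
  m <- matrix(rnorm(42, 20), 7, 6, dimnames = list(paste0("P", 1:7), NULL))
  g <- twoGroups(3)
  o <- samTest(m, g, nPerm = 250, seed = 1)
  # p-values are exact multiples of 1/(20 * nGenes)
  expect_equal(o$p_value * 20 * 7, round(o$p_value * 20 * 7), tolerance = 1e-9)

  # brute-force enumeration oracle
  s0 <- o$s0[1]
  dOf <- function(idx2) {
    m1 <- rowMeans(m[, -idx2]); m2 <- rowMeans(m[, idx2])
    v1 <- apply(m[, -idx2], 1, var); v2 <- apply(m[, idx2], 1, var)
    s <- sqrt((1/3 + 1/3) * ((2 * v1 + 2 * v2) / 4))
    (m2 - m1) / (s + s0)
  }
  nullAbs <- abs(vapply(seq_len(20), function(j) dOf(combn(6, 3)[, j]),
                        numeric(7)))
  pRef <- vapply(abs(dOf(4:6)), function(x) sum(nullAbs >= x), numeric(1)) /
    (20 * 7)
  expect_equal(o$p_value, unname(pRef), tolerance = 1e-12)
})

test_that("SAM with s0 = 0 ranks identically to the pooled t statistic", {
  m <- tinyMatrix(30, 8, seed = 11)
  g <- twoGroups(4)
  o <- samTest(m, g, s0 = 0, seed = 2)
  t0 <- spikeBench:::.rowT(spikeBench:::.groupStats(
    m, rep(c(FALSE, TRUE), each = 4)), pooled = TRUE)$statistic
  expect_identical(order(abs(o$statistic)), order(abs(t0)))
})

test_that("ROTS restricted to the t-like candidate ranks like |t|", {
  m <- tinyMatrix(60, 12, seed = 8)
  g <- twoGroups(6)
  o <- rotsTest(m, g, B = 20, K = 30, candidates = cbind(0, 1), seed = 3)
  t0 <- spikeBench:::.rowT(spikeBench:::.groupStats(
    m, rep(c(FALSE, TRUE), each = 6)), pooled = TRUE)$statistic
  expect_identical(order(-abs(o$statistic)), order(-abs(t0)))
  expect_error(rotsTest(m, g, B = 1), "B")
})

test_that("ROTS selects the mean-difference statistic when it stabilizes rankings", {
  picks <- vapply(1:10, function(s) {
    set.seed(s)
    base <- matrix(rnorm(150 * 12, 20, 1), 150, 12)
    shifted <- matrix(rnorm(50 * 12, 20, 0.02), 50, 12)
    shifted[, 7:12] <- shifted[, 7:12] + rep(runif(50, 5, 8), 6)
    m <- rbind(base, shifted)
    rownames(m) <- paste0("P", seq_len(nrow(m)))
    o <- rotsTest(m, twoGroups(6), B = 30, K = 60, seed = s)
    attr(o, "alpha")[2] == 0
  }, logical(1))
  expect_gte(sum(picks), 8)
})

test_that("two-sided p-values are invariant to reordering and label swap", {
  # 4 + 4 samples keep SAM in its exact-enumeration regime (70 assignments),
  # where the permutation null is a set and hence reorder-invariant
  m <- tinyMatrix(25, 8, seed = 21, naFrac = 0.1)
  g <- factor(twoGroups(4), levels = c("r1:25", "r1:12"))
  gSwap <- factor(g, levels = rev(levels(g)))
  set.seed(99)
  for (mm in c("t_equal", "t_welch", "wilcoxon", "glm_gamma", "limma", "sam")) {
    o <- runTest(m, g, mm, seed = 5)
    # protein reordering
    perm <- sample(nrow(m))
    oPerm <- runTest(m[perm, ], g, mm, seed = 5)
    expect_equal(oPerm$p_value[order(perm)], o$p_value,
                 tolerance = 1e-12, label = paste(mm, "protein reorder"))
    # sample reordering within groups
    shuf <- c(sample(1:4), sample(5:8))
    oShuf <- runTest(m[, shuf], g[shuf], mm, seed = 5)
    expect_equal(oShuf$p_value, o$p_value, tolerance = 1e-12,
                 label = paste(mm, "within-group reorder"))
    # label swap: p unchanged, log2FC negated
    oSwap <- runTest(m, gSwap, mm, seed = 5)
    expect_equal(oSwap$p_value, o$p_value, tolerance = 1e-12,
                 label = paste(mm, "label swap"))
    expect_equal(oSwap$log2fc, -o$log2fc, tolerance = 1e-12)
  }
})

test_that("unknown methods error and fixed seeds reproduce permutation tests", {
  m <- tinyMatrix(10, 8)
  g <- twoGroups(4)
  expect_error(runTest(m, g, "anova"), "method")
  for (mm in c("sam", "rots")) {
    a <- runTest(m, g, mm, params = list(B = 10, K = 10, nPerm = 50), seed = 9)
    b <- runTest(m, g, mm, params = list(B = 10, K = 10, nPerm = 50), seed = 9)
    expect_identical(a, b, label = mm)
  }
})

test_that("SAM has more power than Wilcoxon at n = 3 on strong-signal data", {
  # at n = 3 the exact Wilcoxon two-sided p cannot fall below 0.1, so its
  # sensitivity at alpha = 0.05 is 0; SAM's pooled permutation p-values can
  set.seed(14)
  m <- rbind(matrix(rnorm(200 * 6, 20, 0.5), 200, 6),
             matrix(rnorm(40 * 6, 20, 0.1), 40, 6))
  m[201:240, 4:6] <- m[201:240, 4:6] + 3
  rownames(m) <- c(paste0("H", 1:200), paste0("E", 1:40))
  g <- twoGroups(3)
  pSam <- runTest(m, g, "sam", seed = 2)$p_value[201:240]
  pWil <- runTest(m, g, "wilcoxon")$p_value[201:240]
  expect_gt(mean(pSam < 0.05), mean(pWil < 0.05))
  expect_equal(mean(pWil < 0.05), 0)
})
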