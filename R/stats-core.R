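.TEST_METHODS <- c("t_equal", "t_welch", "wilcoxon", "glm_gamma", "limma",
                   "sam", "rots")

# per-gene observed counts, means and variances for a two-group matrix;
# vectorized via indicator algebra so permutation loops stay cheap
.groupStats <- function(m, g2) {
  O <- !is.na(m)
  X <- m
  X[!O] <- 0
  g1 <- !g2
  n1 <- as.vector(O %*% g1)
  n2 <- as.vector(O %*% g2)
  s1 <- as.vector(X %*% g1)
  s2 <- as.vector(X %*% g2)
  q1 <- as.vector((X * X) %*% g1)
  q2 <- as.vector((X * X) %*% g2)
  m1 <- ifelse(n1 > 0, s1 / n1, NA_real_)
  m2 <- ifelse(n2 > 0, s2 / n2, NA_real_)
  v1 <- ifelse(n1 > 1, pmax(0, (q1 - n1 * m1^2) / (n1 - 1)), NA_real_)
  v2 <- ifelse(n2 > 1, pmax(0, (q2 - n2 * m2^2) / (n2 - 1)), NA_real_)
  list(n1 = n1, n2 = n2, m1 = m1, m2 = m2, v1 = v1, v2 = v2)
}

.asGroupIndicator <- function(groups) {
  # character input: the first group encountered is the reference (group 1);
  # factor input: the first level is the reference
  g <- if (is.factor(groups)) droplevels(groups)
       else factor(groups, levels = unique(groups))
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  list(g2 = as.integer(g) == 2L, levels = levels(g))
}

#' Estimate per-protein log2 fold-changes between two groups
#'
#' log2FC = mean(observed log2, group 2) - mean(observed log2, group 1);
#' `NA` when either group has zero observed values. Group 1 is the first
#' factor level (the reference condition, e.g. `r1:25`).
#'
#' @param mat proteins x samples log2 matrix (`NA` = missing).
#' @param groups two-level factor (or coercible) of length `ncol(mat)`.
#' @return Named numeric vector of log2 fold-changes.
#' @export
#' @examples
#' m <- rbind(p1 = c(20, 20, 21.11, 21.11))
#' estimateLog2FC(m, c("a", "a", "b", "b"))
estimateLog2FC <- function(mat, groups) {
  gi <- .asGroupIndicator(groups)
  st <- .groupStats(mat, gi$g2)
  setNames(st$m2 - st$m1, rownames(mat))
}

# textbook pooled / Satterthwaite two-sample t on precomputed group stats
.rowT <- function(st, pooled = TRUE) {
  if (pooled) {
    df <- st$n1 + st$n2 - 2
    sp2 <- ((st$n1 - 1) * st$v1 + (st$n2 - 1) * st$v2) / df
    se <- sqrt(sp2 * (1 / st$n1 + 1 / st$n2))
  } else {
    a <- st$v1 / st$n1
    b <- st$v2 / st$n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (st$n1 - 1) + b^2 / (st$n2 - 1))
  }
  t <- (st$m2 - st$m1) / se
  # zero variance in both groups: no evidence when the group means agree to
  # numerical precision (group sums may differ by an ulp under BLAS), perfect
  # separation otherwise
  eqMeans <- abs(st$m2 - st$m1) <=
    1e-8 * pmax(abs(st$m1), abs(st$m2), 1)
  t[se == 0 & eqMeans] <- 0
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  p[is.nan(t) | (se == 0 & eqMeans)] <- 1
  p[se == 0 & !eqMeans] <- 0
  list(statistic = t, p = p, df = df)
}

.rowWilcoxon <- function(m, g2) {
  apply(m, 1L, function(x) {
    x1 <- x[!g2][!is.na(x[!g2])]
    x2 <- x[g2][!is.na(x[g2])]
    hasTies <- anyDuplicated(c(x1, x2)) > 0
    exact <- length(x1) <= 8 && length(x2) <= 8 && !hasTies
    suppressWarnings(
      wilcox.test(x2, x1, exact = exact, correct = TRUE)$p.value)
  })
}

# Gamma GLM with log link on 2^x and a two-group factor design: the IRLS
# fixed point is closed-form (fitted means = group means, unit working
# weights), so coef = log(mean2/mean1), var(coef) = phi*(1/n1 + 1/n2) with
# Pearson dispersion phi, and the Wald p uses t with n1 + n2 - 2 df.
.rowGammaGLM <- function(m, g2) {
  y <- 2^m
  st <- .groupStats(y, g2)
  n1 <- st$n1; n2 <- st$n2
  coef <- log(st$m2 / st$m1)
  O <- !is.na(y)
  Y <- y; Y[!O] <- 0
  mu <- outer(st$m1, as.numeric(!g2)) + outer(st$m2, as.numeric(g2))
  pearson <- ((Y - mu) / mu)^2
  pearson[!O] <- 0
  df <- n1 + n2 - 2
  phi <- rowSums(pearson) / df
  se <- sqrt(phi * (1 / n1 + 1 / n2))
  t <- coef / se
  zeroCoef <- abs(coef) <= 1e-8   # log scale: relative ulp noise in the means
  t[se == 0 & zeroCoef] <- 0
  p <- 2 * pt(abs(t), df, lower.tail = FALSE)
  p[se == 0 & zeroCoef] <- 1
  p[se == 0 & !zeroCoef & !is.na(coef)] <- 0
  list(coef = coef, p = p)
}

#' Run a two-group differential-abundance test on every protein
#'
#' The uniform missing-data policy: a protein needs at least two observed
#' values in each group to be tested; otherwise its status is
#' `insufficient_data` and its p-value is left `NA` (coerced to 1 at
#' evaluation time). No imputation is performed anywhere. All tests are
#' two-sided.
#'
#' @param mat proteins x samples log2 matrix (`NA` = missing) or a
#'   [SpikeInExperiment-class] restricted to two conditions.
#' @param groups two-level factor of length `ncol(mat)`; the first level is
#'   the reference group. Ignored (taken from the condition annotation) when
#'   `mat` is a `SpikeInExperiment`.
#' @param method one of `"t_equal"`, `"t_welch"`, `"wilcoxon"`,
#'   `"glm_gamma"`, `"limma"` (empirical-Bayes moderated t), `"sam"`,
#'   `"rots"`.
#' @param params method parameters: for `sam` see [samTest()]
#'   (`nPerm`), for `rots` see [rotsTest()] (`B`, `K`).
#' @param seed integer seed for the permutation/bootstrap methods.
#' @return A `data.frame` with columns `protein`, `p_value`, `log2fc`,
#'   `status` (`tested` / `insufficient_data`).
#' @export
#' @examples
#' m <- matrix(rnorm(60, 20), 10, 6,
#'             dimnames = list(paste0("P", 1:10), paste0("s", 1:6)))
#' runTest(m, rep(c("r1:25", "r1:12"), each = 3), "t_welch")
runTest <- function(mat, groups = NULL,
                    method = c("t_equal", "t_welch", "wilcoxon", "glm_gamma",
                               "limma", "sam", "rots"),
                    params = list(), seed = 1L) {
  if (is(mat, "SpikeInExperiment")) {
    if (is.null(groups)) groups <- sampleConditions(mat)
    mat <- intensities(mat)
  }
  if (is.character(method) && length(method) == 1 &&
      !method %in% .TEST_METHODS) {
    stop(sprintf("unknown method '%s'", method))
  }
  method <- match.arg(method)
  gi <- .asGroupIndicator(groups)
  g2 <- gi$g2
  st <- .groupStats(mat, g2)
  testable <- st$n1 >= 2 & st$n2 >= 2
  log2fc <- st$m2 - st$m1

  p <- rep(NA_real_, nrow(mat))
  if (any(testable)) {
    sub <- mat[testable, , drop = FALSE]
    p[testable] <- switch(method,
      t_equal = .rowT(.groupStats(sub, g2), pooled = TRUE)$p,
      t_welch = .rowT(.groupStats(sub, g2), pooled = FALSE)$p,
      wilcoxon = .rowWilcoxon(sub, g2),
      glm_gamma = .rowGammaGLM(sub, g2)$p,
      limma = moderatedTTest(sub, groups)$p_value,
      sam = samTest(sub, groups, nPerm = params$nPerm %||% 250,
                    seed = seed)$p_value,
      rots = rotsTest(sub, groups, B = params$B %||% 100,
                      K = params$K %||% 500, seed = seed)$p_value
    )
  }
  data.frame(
    protein = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    p_value = p, log2fc = log2fc,
    status = ifelse(testable, "tested", "insufficient_data"),
    row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
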