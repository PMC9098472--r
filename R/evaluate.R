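#' Build the three reference protein lists from an ensemble of protein sets
#'
#' `combined` is the union over workflows; `intersection` contains the
#' proteins appearing in more than `threshold` of the workflows, implemented
#' as a count floor: membership count >= `floor(threshold * W) + 1` (for
#' W = 17 and threshold 0.8 this is "at least 14 of 17").
#'
#' @param sets a [WorkflowEnsemble-class] or a (named) list of character
#'   protein sets.
#' @param threshold membership fraction for the intersection list (default
#'   0.8, strict).
#' @return A list with `workflow` (the per-workflow sets), `combined`,
#'   `intersection`, `threshold`, `minCount`.
#' @export
#' @examples
#' buildReferenceLists(list(w1 = c("A", "B"), w2 = c("B", "C"), w3 = "B"))
buildReferenceLists <- function(sets, threshold = 0.8) {
  if (is(sets, "WorkflowEnsemble")) {
    sets <- lapply(ensembleDatasets(sets), rownames)
  }
  if (!length(sets)) stop("empty ensemble")
  W <- length(sets)
  counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
  minCount <- floor(threshold * W) + 1
  list(workflow = sets,
       combined = sort(names(counts)),
       intersection = sort(names(counts)[counts >= minCount]),
       threshold = threshold, minCount = minCount)
}

# reference split into positives (spike) / negatives (human); shared
# precondition checks for the ROC-based measures
.referenceSplit <- function(truth, reference) {
  sp <- proteinSpecies(truth)[reference]
  if (anyNA(sp)) {
    stop("reference contains protein(s) without ground truth")
  }
  pos <- reference[sp == "ecoli"]
  neg <- reference[sp == "human"]
  if (!length(pos) || !length(neg)) {
    stop("reference must contain proteins of both species")
  }
  list(positives = pos, negatives = neg)
}

# p-values of reference proteins present in the outcome (missing coerced to
# 1); absent proteins are never called (permanent FN/TN)
.referenceP <- function(outcome, reference) {
  p <- setNames(outcome$p_value, outcome$protein)
  p[is.na(p)] <- 1
  p[intersect(reference, names(p))]
}

#' Build a ROC curve from a test outcome against the ground truth
#'
#' Positives are the spike proteins of the reference list, negatives the
#' human proteins. Reference proteins absent from the outcome are permanent
#' false/true negatives — they are never called, capping the maximum TPR (the
#' mechanism behind the 'Combined' list cap). Proteins present with a missing
#' p-value get p = 1. Thresholds sweep the distinct p-values ascending
#' (call = p <= threshold); ties advance TP and FP jointly in one vertex.
#'
#' @param outcome `data.frame` from [runTest()] (columns `protein`,
#'   `p_value`).
#' @param truth a [GroundTruth-class].
#' @param reference character vector of reference proteins.
#' @return A `data.frame` with columns `threshold`, `fpr`, `tpr`, anchored at
#'   (0, 0).
#' @export
rocPoints <- function(outcome, truth, reference) {
  split <- .referenceSplit(truth, reference)
  p <- .referenceP(outcome, reference)
  isPos <- names(p) %in% split$positives
  thr <- sort(unique(p))
  tp <- vapply(thr, function(t) sum(p[isPos] <= t), numeric(1))
  fp <- vapply(thr, function(t) sum(p[!isPos] <= t), numeric(1))
  data.frame(threshold = c(NA_real_, thr),
             fpr = c(0, fp / length(split$negatives)),
             tpr = c(0, tp / length(split$positives)))
}

#' Scaled partial AUC below a false-positive-rate ceiling
#'
#' Trapezoidal area under the ROC curve restricted to `fpr <= fprMax`, with
#' linear interpolation of the TPR at `fprMax` when no vertex falls there,
#' scaled by `100 / fprMax` so a perfect classifier scores 100. If the
#' attainable terminal FPR is below `fprMax` the curve is extended
#' horizontally at the terminal TPR (absent negatives are never called).
#'
#' @param curve `data.frame` from [rocPoints()] (columns `fpr`, `tpr`).
#' @param fprMax FPR ceiling in (0, 1\] (default 0.1).
#' @return Scaled pAUC in \[0, 100\].
#' @export
#' @examples
#' perfect <- data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))
#' pauc(perfect)
pauc <- function(curve, fprMax = 0.1) {
  if (fprMax <= 0 || fprMax > 1) stop("fprMax must be in (0, 1]")
  fpr <- curve$fpr
  tpr <- curve$tpr
  if (is.unsorted(fpr) || is.unsorted(tpr)) {
    stop("ROC curve must be non-decreasing in both coordinates")
  }
  if (max(fpr) < fprMax) {
    fpr <- c(fpr, fprMax)
    tpr <- c(tpr, tpr[length(tpr)])
  } else if (!any(fpr == fprMax)) {
    i <- which(fpr > fprMax)[1]
    w <- (fprMax - fpr[i - 1]) / (fpr[i] - fpr[i - 1])
    fpr <- c(fpr[seq_len(i - 1)], fprMax)
    tpr <- c(tpr[seq_len(i - 1)], tpr[i - 1] + w * (tpr[i] - tpr[i - 1]))
  } else {
    keep <- fpr <= fprMax
    fpr <- fpr[keep]
    tpr <- tpr[keep]
  }
  area <- sum(diff(fpr) * (head2(tpr) + diff(tpr) / 2))
  100 * area / fprMax
}

head2 <- function(x) x[-length(x)]

#' Sensitivity at a significance level
#'
#' Fraction of reference spike proteins with p below `alpha` (strict).
#' Reference spike proteins absent from the outcome, or with a missing
#' p-value, count in the denominator only.
#'
#' @inheritParams rocPoints
#' @param alpha significance level (default 0.05).
#' @return Fraction in \[0, 1\].
#' @export
sensitivityAt <- function(outcome, truth, reference, alpha = 0.05) {
  split <- .referenceSplit(truth, reference)
  p <- .referenceP(outcome, reference)
  sum(p[names(p) %in% split$positives] < alpha) / length(split$positives)
}

#' Confusion counts at a significance level
#'
#' @inheritParams sensitivityAt
#' @return One-row `data.frame` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusionAt <- function(outcome, truth, reference, alpha = 0.05) {
  split <- .referenceSplit(truth, reference)
  p <- .referenceP(outcome, reference)
  isPos <- names(p) %in% split$positives
  tp <- sum(p[isPos] < alpha)
  fp <- sum(p[!isPos] < alpha)
  data.frame(tp = tp, fp = fp,
             tn = length(split$negatives) - fp,
             fn = length(split$positives) - tp)
}

#' RMSE of the estimated log2 fold-changes against the ground truth
#'
#' Root-mean-square error over the reference proteins with a defined
#' estimate; proteins without an estimate are excluded and counted.
#'
#' @param outcome `data.frame` from [runTest()] (columns `protein`,
#'   `log2fc`).
#' @param truth a [GroundTruth-class].
#' @param reference character vector of reference proteins.
#' @return A list with `rmse` and `nExcluded`.
#' @export
rmseLog2FC <- function(outcome, truth, reference) {
  est <- setNames(outcome$log2fc, outcome$protein)
  est <- est[intersect(reference, names(est))]
  truthFC <- trueLog2FC(truth)
  absent <- sum(!reference %in% names(est))
  defined <- !is.na(est)
  if (!any(defined)) stop("no reference protein has a defined estimate")
  err <- est[defined] - truthFC[names(est)[defined]]
  list(rmse = sqrt(mean(err^2)), nExcluded = absent + sum(!defined))
}

#' Evaluate a test outcome against one reference list
#'
#' Convenience wrapper computing scaled pAUC, sensitivity at `alpha`,
#' confusion counts and RMSE in one pass.
#'
#' @inheritParams rocPoints
#' @param fprMax FPR ceiling for [pauc()].
#' @param alpha significance level for [sensitivityAt()].
#' @return One-row `data.frame` with `pauc`, `sensitivity`, `rmse`,
#'   `n_excluded`, `tp`, `fp`, `tn`, `fn`.
#' @export
evaluateOutcome <- function(outcome, truth, reference, fprMax = 0.1,
                            alpha = 0.05) {
  curve <- rocPoints(outcome, truth, reference)
  rmse <- tryCatch(rmseLog2FC(outcome, truth, reference),
                   error = function(e) list(rmse = NA_real_,
                                            nExcluded = length(reference)))
  cbind(data.frame(pauc = pauc(curve, fprMax),
                   sensitivity = sensitivityAt(outcome, truth, reference, alpha),
                   rmse = rmse$rmse, n_excluded = rmse$nExcluded),
        confusionAt(outcome, truth, reference, alpha))
}

#' Per-protein and per-sample missingness profile
#'
#' For every protein: mean observed log2 intensity, missing fraction and
#' species; for every sample: mean observed intensity, missing fraction and
#' condition; plus Pearson and Spearman correlations between mean intensity
#' and missing fraction for both views (`NA` with `defined = FALSE` when a
#' view is constant, e.g. a complete matrix).
#'
#' @param x a [SpikeInExperiment-class].
#' @return A list with `proteins`, `samples` (data.frames) and `correlations`.
#' @export
missingnessProfile <- function(x) {
  m <- intensities(x)
  prot <- data.frame(
    protein = rownames(m),
    mean_intensity = rowMeans(m, na.rm = TRUE),
    missing_fraction = rowMeans(is.na(m)),
    species = proteinSpecies(x), row.names = NULL)
  samp <- data.frame(
    sample = colnames(m),
    mean_intensity = colMeans(m, na.rm = TRUE),
    missing_fraction = colMeans(is.na(m)),
    condition = sampleConditions(x), row.names = NULL)
  corSafe <- function(a, b, method) {
    if (sd(a, na.rm = TRUE) == 0 || sd(b, na.rm = TRUE) == 0 ||
        all(is.na(a)) || all(is.na(b))) return(NA_real_)
    cor(a, b, use = "complete.obs", method = method)
  }
  correlations <- data.frame(
    view = rep(c("protein", "sample"), each = 2),
    method = rep(c("pearson", "spearman"), 2),
    estimate = c(
      corSafe(prot$mean_intensity, prot$missing_fraction, "pearson"),
      corSafe(prot$mean_intensity, prot$missing_fraction, "spearman"),
      corSafe(samp$mean_intensity, samp$missing_fraction, "pearson"),
      corSafe(samp$mean_intensity, samp$missing_fraction, "spearman")))
  correlations$defined <- !is.na(correlations$estimate)
  list(proteins = prot, samples = samp, correlations = correlations)
}
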