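# tiny deterministic fixtures used across the suite

tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(nHuman = 60, nSpike = 15, nPerCondition = 6, seed = 101)
  do.call(simConfig, utils::modifyList(defaults, args))
}

# noiseless configuration: no biological/technical noise, no missingness
noiselessConfig <- function(...) {
  tinyConfig(sigmaPatientHuman = 0, sigmaPatientSpike = 0, techSd = 0,
             mcarRate = 0, fpRate = 0, detectMu = -1000, detectSd = 0,
             detectSlope = Inf, ...)
}

tinyMatrix <- function(nProt = 8, nSamp = 6, seed = 1, naFrac = 0) {
  set.seed(seed)
  m <- matrix(rnorm(nProt * nSamp, 20, 1), nProt, nSamp,
              dimnames = list(sprintf("P%02d", seq_len(nProt)),
                              sprintf("s%02d", seq_len(nSamp))))
  if (naFrac > 0) m[sample(length(m), round(naFrac * length(m)))] <- NA
  m
}

twoGroups <- function(nPer = 3) rep(c("r1:25", "r1:12"), each = nPer)

# a hand-specified ground truth for evaluation tests
handTruth <- function(proteins, species) {
  GroundTruth(protein = proteins, species = species,
              trueLog2FC = ifelse(species == "ecoli", 1.11, 0),
              presentIn = lapply(species, function(s) {
                if (s == "ecoli") c("r1:25", "r1:12", "r1:6")
                else c("humanOnly", "r1:25", "r1:12", "r1:6")
              }))
}

# independent brute-force scaled pAUC oracle: exhaustive threshold
# enumeration with explicit counting loops, trapezoid via stats::approx
bruteForcePauc <- function(p, isPositive, nPos, nNeg, fprMax = 0.1) {
  p[is.na(p)] <- 1
  thr <- sort(unique(p))
  fpr <- 0
  tpr <- 0
  for (t in thr) {
    tp <- 0
    fp <- 0
    for (i in seq_along(p)) {
      if (p[i] <= t) {
        if (isPositive[i]) tp <- tp + 1 else fp <- fp + 1
      }
    }
    fpr <- c(fpr, fp / nNeg)
    tpr <- c(tpr, tp / nPos)
  }
  if (max(fpr) < fprMax) {
    fpr <- c(fpr, fprMax)
    tpr <- c(tpr, tpr[length(tpr)])
  }
  area <- 0
  for (i in seq_len(length(fpr) - 1)) {
    x1 <- fpr[i]; x2 <- fpr[i + 1]; y1 <- tpr[i]; y2 <- tpr[i + 1]
    if (x1 >= fprMax) break
    if (x2 > fprMax) {
      y2 <- y1 + (y2 - y1) * (fprMax - x1) / (x2 - x1)
      x2 <- fprMax
    }
    area <- area + (x2 - x1) * (y1 + y2) / 2
  }
  100 * area / fprMax
}
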