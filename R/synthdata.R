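#' SimConfig: parameters of the two-species spike-in simulator
#'
#' All intensities are on the log2 scale. The simulator emulates a benchmark
#' design with a heterogeneous human tissue background measured in four
#' spike-in conditions (`humanOnly`, `r1:25`, `r1:12`, `r1:6`), a single-batch
#' bacterial spike-in whose proteins shift by a known log2 fold-change between
#' conditions, and intensity-dependent (MNAR) missingness driven by
#' sample-specific detection thresholds.
#'
#' @slot nHuman,nSpike protein counts per species.
#' @slot nPerCondition samples per condition (default 23).
#' @slot conditions ordered condition labels.
#' @slot baseMean,baseSd location/scale of the per-protein baseline log2
#'   intensity.
#' @slot sigmaPatientHuman,sigmaPatientSpike scale of the per-protein
#'   biological SD on the log2 scale (human background much larger than the
#'   single-batch spike).
#' @slot varLogSd spread of the per-protein log2 variances: each protein's
#'   biological variance is its species scale squared times
#'   `2^(varLogSd * Z)`, `Z ~ N(0,1)`; 0 gives homogeneous variances.
#' @slot techSd technical noise SD.
#' @slot spikeDelta true log2 shift of spike proteins between `r1:25` and
#'   `r1:12` (default 1.11).
#' @slot delta1to6 log2 shift of `r1:6` relative to `r1:25` (default
#'   `spikeDelta + 1`, the measured 1:12 shift plus the exact twofold step).
#' @slot detectMu,detectSd mean and SD of the per-sample detection-threshold
#'   location.
#' @slot detectSlope steepness of the logistic detection curve; `Inf` gives a
#'   hard threshold.
#' @slot mcarRate uniform random missingness rate in \[0,1\].
#' @slot fpRate probability that a spike protein is spuriously reported in a
#'   human-only sample.
#' @slot seed integer RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(nHuman = "numeric", nSpike = "numeric",
                 nPerCondition = "numeric", conditions = "character",
                 baseMean = "numeric", baseSd = "numeric",
                 sigmaPatientHuman = "numeric", sigmaPatientSpike = "numeric",
                 varLogSd = "numeric", techSd = "numeric", spikeDelta = "numeric",
                 delta1to6 = "numeric", detectMu = "numeric",
                 detectSd = "numeric", detectSlope = "numeric",
                 mcarRate = "numeric", fpRate = "numeric", seed = "numeric"))

setValidity("SimConfig", function(object) {
  bad <- function(field, ok) if (ok) character(0) else field
  msg <- c(
    bad("nHuman", length(object@nHuman) == 1 && object@nHuman >= 1),
    bad("nSpike", length(object@nSpike) == 1 && object@nSpike >= 1),
    bad("nPerCondition", length(object@nPerCondition) == 1 && object@nPerCondition >= 1),
    bad("conditions", "humanOnly" %in% object@conditions &&
          all(c("r1:25", "r1:12") %in% object@conditions)),
    bad("baseSd", object@baseSd >= 0),
    bad("sigmaPatientHuman", object@sigmaPatientHuman >= 0),
    bad("sigmaPatientSpike", object@sigmaPatientSpike >= 0),
    bad("varLogSd", object@varLogSd >= 0),
    bad("techSd", object@techSd >= 0),
    bad("detectSd", object@detectSd >= 0),
    bad("detectSlope", object@detectSlope >= 0),
    bad("mcarRate", object@mcarRate >= 0 && object@mcarRate <= 1),
    bad("fpRate", object@fpRate >= 0 && object@fpRate <= 1),
    bad("seed", length(object@seed) == 1 && !is.na(object@seed))
  )
  if (length(msg)) sprintf("invalid configuration field(s): %s",
                           paste(msg, collapse = ", ")) else TRUE
})

#' Build a simulator configuration
#'
#' Defaults describe the desk-scale benchmark: 1000 human + 200 spike
#' proteins, four conditions of 23 samples, spike log2FC 1.11 between the two
#' lowest spike-in ratios, heterogeneous human background
#' (`sigmaPatientHuman` = 1) versus a low-variance single-batch spike
#' (`sigmaPatientSpike` = 0.25), per-protein variance dispersion spanning
#' several orders of magnitude (`varLogSd` = 2, matching the wide per-protein
#' log2-variance distributions of real label-free data), and logistic MNAR
#' missingness around sample-specific detection thresholds.
#'
#' @param nHuman,nSpike,nPerCondition,conditions,baseMean,baseSd see
#'   [SimConfig-class].
#' @param sigmaPatientHuman,sigmaPatientSpike,varLogSd,techSd see
#'   [SimConfig-class].
#' @param spikeDelta,delta1to6 see [SimConfig-class].
#' @param detectMu,detectSd,detectSlope,mcarRate,fpRate,seed see
#'   [SimConfig-class].
#' @return A validated [SimConfig-class] object.
#' @export
#' @examples
#' cfg <- simConfig(nHuman = 50, nSpike = 10, nPerCondition = 5, seed = 7)
#' sim <- simulateBenchmark(cfg)
#' sim$dataset
simConfig <- function(nHuman = 1000, nSpike = 200, nPerCondition = 23,
                      conditions = c("humanOnly", "r1:25", "r1:12", "r1:6"),
                      baseMean = 20, baseSd = 2.5,
                      sigmaPatientHuman = 1, sigmaPatientSpike = 0.25,
                      varLogSd = 2, techSd = 0.2, spikeDelta = 1.11,
                      delta1to6 = spikeDelta + 1,
                      detectMu = 17.5, detectSd = 0.75, detectSlope = 1.5,
                      mcarRate = 0.02, fpRate = 0, seed = 1) {
  new("SimConfig", nHuman = nHuman, nSpike = nSpike,
      nPerCondition = nPerCondition, conditions = conditions,
      baseMean = baseMean, baseSd = baseSd,
      sigmaPatientHuman = sigmaPatientHuman,
      sigmaPatientSpike = sigmaPatientSpike, varLogSd = varLogSd,
      techSd = techSd,
      spikeDelta = spikeDelta, delta1to6 = delta1to6, detectMu = detectMu,
      detectSd = detectSd, detectSlope = detectSlope, mcarRate = mcarRate,
      fpRate = fpRate, seed = seed)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d human + %d spike proteins, %d samples x %d conditions, seed %d\n",
              object@nHuman, object@nSpike, object@nPerCondition,
              length(object@conditions), as.integer(object@seed)))
  cat(sprintf("  spikeDelta %.3f | detect N(%.2f, %.2f) slope %.2f | mcar %.3f fp %.3f\n",
              object@spikeDelta, object@detectMu, object@detectSd,
              object@detectSlope, object@mcarRate, object@fpRate))
})

# complete (pre-missingness) matrix + structural presence map; shared by the
# single-benchmark and ensemble generators so members reuse one simulation
.simulateComplete <- function(config) {
  proteins <- c(sprintf("HSA%04d_HUMAN", seq_len(config@nHuman)),
                sprintf("ECO%04d_ECOLI", seq_len(config@nSpike)))
  species <- c(rep("human", config@nHuman), rep("ecoli", config@nSpike))
  nCond <- length(config@conditions)
  nSamp <- config@nPerCondition * nCond
  samples <- sprintf("S%03d", seq_len(nSamp))
  condition <- rep(config@conditions, each = config@nPerCondition)

  set.seed(deriveSeed(config@seed, "baselines"))
  baseline <- rnorm(length(proteins), config@baseMean, config@baseSd)

  shift <- matrix(0, length(proteins), nSamp,
                  dimnames = list(proteins, samples))
  spike <- species == "ecoli"
  shift[spike, condition == "r1:12"] <- config@spikeDelta
  if ("r1:6" %in% config@conditions) {
    shift[spike, condition == "r1:6"] <- config@delta1to6
  }

  # per-protein biological SD: species scale with lognormal dispersion, so
  # the per-protein log2 variances span a wide, roughly symmetric range as in
  # real label-free protein quantitation
  set.seed(deriveSeed(config@seed, "varspread"))
  sigmaScale <- ifelse(spike, config@sigmaPatientSpike,
                       config@sigmaPatientHuman)
  sigma <- sigmaScale * 2^(config@varLogSd * rnorm(length(proteins)) / 2)

  set.seed(deriveSeed(config@seed, "patient"))
  patient <- matrix(rnorm(length(shift), 0, rep(sigma, nSamp)),
                    nrow = length(proteins))

  set.seed(deriveSeed(config@seed, "technical"))
  tech <- matrix(rnorm(length(shift), 0, config@techSd), nrow = length(proteins))

  complete <- baseline + shift + patient + tech
  dimnames(complete) <- list(proteins, samples)

  list(complete = complete, species = species, condition = condition,
       spike = spike, proteins = proteins, samples = samples)
}

# member-indexed observation layer: thresholds + MNAR/MCAR + structural
# absence + false-positive injection.  member 1 is the canonical benchmark.
.observe <- function(complete, sim, config, member = 1L) {
  set.seed(deriveSeed(config@seed, "thresholds", member))
  thresholds <- rnorm(length(sim$samples), config@detectMu, config@detectSd)

  set.seed(deriveSeed(config@seed, "missingness", member))
  observed <- applyMissingness(complete, config, thresholds)

  humanOnly <- sim$condition == "humanOnly"
  observed[sim$spike, humanOnly] <- NA_real_

  if (config@fpRate > 0 && any(sim$spike) && any(humanOnly)) {
    set.seed(deriveSeed(config@seed, "falsepositives", member))
    nCells <- sum(sim$spike) * sum(humanOnly)
    hit <- matrix(runif(nCells) < config@fpRate, nrow = sum(sim$spike))
    # spurious identifications sit just above the detection limit
    fpInt <- matrix(rep(thresholds[humanOnly], each = sum(sim$spike)) +
                      abs(rnorm(nCells, 0, 1)), nrow = sum(sim$spike))
    block <- observed[sim$spike, humanOnly, drop = FALSE]
    block[hit] <- fpInt[hit]
    observed[sim$spike, humanOnly] <- block
  }
  observed
}

#' Simulate a labelled two-species spike-in benchmark dataset
#'
#' Per-protein realized intensity = baseline + condition shift + patient
#' effect + technical noise, then passed through [applyMissingness()] with
#' sample-specific detection thresholds. Spike proteins are structurally
#' absent from `humanOnly` samples; with `fpRate > 0` they are spuriously
#' reported there with that probability. Identical seeds give bit-identical
#' output.
#'
#' @param config a [SimConfig-class].
#' @return A list with elements `dataset` ([SpikeInExperiment-class]) and
#'   `truth` ([GroundTruth-class]).
#' @export
#' @examples
#' sim <- simulateBenchmark(simConfig(nHuman = 40, nSpike = 8,
#'                                    nPerCondition = 4, seed = 3))
#' table(proteinSpecies(sim$dataset))
simulateBenchmark <- function(config) {
  validObject(config)
  sim <- .simulateComplete(config)
  observed <- .observe(sim$complete, sim, config, member = 1L)

  dataset <- SpikeInExperiment(observed, species = sim$species,
                               condition = sim$condition,
                               metadata = list(config = config))
  presentIn <- lapply(sim$spike, function(isSpike) {
    if (isSpike) setdiff(config@conditions, "humanOnly") else config@conditions
  })
  truth <- GroundTruth(protein = sim$proteins, species = sim$species,
                       trueLog2FC = ifelse(sim$spike, config@spikeDelta, 0),
                       presentIn = presentIn,
                       comparedConditions = c("r1:25", "r1:12"))
  list(dataset = dataset, truth = truth)
}

#' Apply MNAR + MCAR missingness to a complete log2 intensity matrix
#'
#' Cell (g, s) is set missing with probability
#' `plogis((thresholds[s] - x[g, s]) * detectSlope)`, then additionally with
#' probability `mcarRate`. The mechanism is monotone: lowering an intensity
#' never decreases its missingness probability. An infinite slope gives a
#' hard threshold (missing below, observed above, fair coin exactly at the
#' threshold). Draws come from the current RNG state; callers seed it.
#'
#' @param mat complete numeric matrix of log2 intensities.
#' @param config a [SimConfig-class] providing `detectSlope` and `mcarRate`.
#' @param thresholds numeric vector, one detection threshold per sample.
#' @return `mat` with missing cells set to `NA`.
#' @export
applyMissingness <- function(mat, config, thresholds) {
  if (length(thresholds) != ncol(mat)) {
    stop("need exactly one threshold per sample")
  }
  if (anyNA(mat)) stop("input matrix must be complete")
  delta <- sweep(-mat, 2, thresholds, "+")   # T_s - x_gs
  if (is.infinite(config@detectSlope)) {
    pMiss <- (delta > 0) + 0.5 * (delta == 0)
  } else {
    pMiss <- plogis(delta * config@detectSlope)
  }
  miss <- matrix(runif(length(mat)) < pMiss, nrow = nrow(mat))
  if (config@mcarRate > 0) {
    miss <- miss | matrix(runif(length(mat)) < config@mcarRate, nrow = nrow(mat))
  }
  mat[miss] <- NA_real_
  mat
}

#' Simulate an ensemble of pseudo-workflow views of one benchmark
#'
#' Emulates the situation where several acquisition/search workflows quantify
#' overlapping but non-identical protein sets from the same samples: each
#' member applies an independent per-workflow protein dropout (retention rate
#' drawn uniformly from `[1 - dropoutSpread, 1]`) and an independent
#' detection-threshold re-draw to one shared underlying simulation. Member 1
#' with `dropoutSpread = 0` equals the [simulateBenchmark()] output.
#'
#' @param config a [SimConfig-class].
#' @param nWorkflows number of members (>= 1).
#' @param dropoutSpread fraction in `[0, 1)` controlling how much the member
#'   protein sets may shrink.
#' @return A [WorkflowEnsemble-class].
#' @export
simulateWorkflowEnsemble <- function(config, nWorkflows = 17,
                                     dropoutSpread = 0.2) {
  validObject(config)
  if (nWorkflows < 1) stop("nWorkflows must be >= 1")
  if (dropoutSpread < 0 || dropoutSpread >= 1) {
    stop("dropoutSpread must be in [0, 1)")
  }
  sim <- .simulateComplete(config)
  base <- simulateBenchmark(config)

  datasets <- vector("list", nWorkflows)
  labels <- sprintf("workflow%02d", seq_len(nWorkflows))
  for (w in seq_len(nWorkflows)) {
    observed <- if (w == 1L) intensities(base$dataset)
                else .observe(sim$complete, sim, config, member = w)
    set.seed(deriveSeed(config@seed, "dropout", w))
    retention <- runif(1, 1 - dropoutSpread, 1)
    keep <- runif(nrow(observed)) <= retention
    if (!any(keep)) keep[sample(nrow(observed), 1L)] <- TRUE
    datasets[[w]] <- SpikeInExperiment(
      observed[keep, , drop = FALSE], species = sim$species[keep],
      condition = sim$condition,
      metadata = list(workflow = labels[w], retention = retention))
  }
  new("WorkflowEnsemble", labels = labels, datasets = datasets,
      truth = base$truth)
}
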