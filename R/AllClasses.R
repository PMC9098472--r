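#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
NULL

.SPECIES_LEVELS <- c("human", "ecoli", "ambiguous")

#' SpikeInExperiment: a two-species protein intensity matrix
#'
#' Container for a proteins x samples log2 intensity matrix with missing
#' values coded as `NA`, a species label per protein (`human`, `ecoli` or
#' `ambiguous`) and a spike-in condition per sample. Extends
#' [SummarizedExperiment::SummarizedExperiment] so the full Bioconductor
#' subsetting/accessor machinery applies.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @name SpikeInExperiment-class
#' @aliases SpikeInExperiment-class
#' @exportClass SpikeInExperiment
setClass("SpikeInExperiment", contains = "SummarizedExperiment")

setValidity("SpikeInExperiment", function(object) {
  msg <- character(0)
  if (!"log2intensity" %in% assayNames(object)) {
    msg <- c(msg, "assay 'log2intensity' is required")
  } else {
    a <- assay(object, "log2intensity")
    if (!is.numeric(a)) msg <- c(msg, "'log2intensity' must be numeric")
    else if (any(is.infinite(a))) msg <- c(msg, "intensities must be finite on the log2 scale")
  }
  rn <- rownames(object)
  cn <- colnames(object)
  if (is.null(rn) || anyDuplicated(rn)) msg <- c(msg, "protein ids must be unique and non-NULL")
  if (is.null(cn) || anyDuplicated(cn)) msg <- c(msg, "sample ids must be unique and non-NULL")
  if (!"species" %in% colnames(rowData(object))) {
    msg <- c(msg, "rowData must contain a 'species' column")
  } else if (!all(rowData(object)$species %in% .SPECIES_LEVELS)) {
    msg <- c(msg, sprintf("species must be one of: %s", paste(.SPECIES_LEVELS, collapse = ", ")))
  }
  if (!"condition" %in% colnames(colData(object))) {
    msg <- c(msg, "colData must contain a 'condition' column")
  } else if (anyNA(colData(object)$condition)) {
    msg <- c(msg, "every sample must be annotated with a condition")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeInExperiment
#'
#' @param intensity numeric matrix of log2 intensities (proteins x samples,
#'   `NA` = missing) with row and column names.
#' @param species character vector, one of `"human"`, `"ecoli"`,
#'   `"ambiguous"` per protein. Parsed from the row names via
#'   [parseSpecies()] when omitted.
#' @param condition character vector of spike-in condition labels, one per
#'   sample.
#' @param metadata optional list stored in the object metadata.
#' @return A [SpikeInExperiment-class] object.
#' @export
#' @examples
#' m <- matrix(c(20, 21, NA, 19), 2, 2,
#'             dimnames = list(c("ALBU_HUMAN", "DNAK_ECOLI"), c("s1", "s2")))
#' se <- SpikeInExperiment(m, condition = c("r1:25", "r1:12"))
#' proteinSpecies(se)
SpikeInExperiment <- function(intensity, species = NULL, condition,
                              metadata = list()) {
  intensity <- as.matrix(intensity)
  if (is.null(species)) species <- parseSpecies(rownames(intensity))
  se <- SummarizedExperiment(
    assays = list(log2intensity = intensity),
    rowData = DataFrame(species = species, row.names = rownames(intensity)),
    colData = DataFrame(condition = as.character(condition),
                        row.names = colnames(intensity)),
    metadata = metadata
  )
  new("SpikeInExperiment", se)
}

#' GroundTruth: known differential status of every simulated protein
#'
#' Records, for the compared condition pair, the true log2 fold-change per
#' protein (0 for the human background, the spike shift for E. coli-like
#' proteins) and the set of conditions in which each protein is physically
#' present.
#'
#' @slot protein character, unique protein ids.
#' @slot species character, `"human"` or `"ecoli"` per protein.
#' @slot trueLog2FC numeric, true log2 fold-change per protein for the
#'   compared pair.
#' @slot presentIn list of character vectors of condition labels.
#' @slot comparedConditions character(2), the (reference, treatment) pair.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(protein = "character", species = "character",
                 trueLog2FC = "numeric", presentIn = "list",
                 comparedConditions = "character"))

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  n <- length(object@protein)
  if (anyDuplicated(object@protein)) msg <- c(msg, "protein ids must be unique")
  if (length(object@species) != n || length(object@trueLog2FC) != n ||
      length(object@presentIn) != n) {
    msg <- c(msg, "protein, species, trueLog2FC and presentIn must have equal length")
  }
  if (!all(object@species %in% c("human", "ecoli"))) {
    msg <- c(msg, "ground-truth species must be 'human' or 'ecoli'")
  }
  if (length(object@comparedConditions) != 2L) {
    msg <- c(msg, "comparedConditions must name exactly two conditions")
  }
  spike <- object@species == "ecoli"
  if (any(vapply(object@presentIn[spike],
                 function(p) "humanOnly" %in% p, logical(1)))) {
    msg <- c(msg, "spike proteins cannot be present in the humanOnly condition")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GroundTruth object
#'
#' @param protein,species,trueLog2FC,presentIn,comparedConditions see slots of
#'   [GroundTruth-class].
#' @return A [GroundTruth-class] object.
#' @export
GroundTruth <- function(protein, species, trueLog2FC, presentIn,
                        comparedConditions = c("r1:25", "r1:12")) {
  new("GroundTruth", protein = as.character(protein),
      species = as.character(species),
      trueLog2FC = as.numeric(trueLog2FC), presentIn = presentIn,
      comparedConditions = as.character(comparedConditions))
}

#' WorkflowEnsemble: one simulation observed through several pseudo-workflows
#'
#' An ordered collection of (label, dataset) pairs sharing one underlying
#' simulation and one sample annotation; the member protein sets may differ
#' (that is the point: it stands in for the per-software protein lists a real
#' multi-workflow benchmark produces).
#'
#' @slot labels character, one label per member.
#' @slot datasets list of [SpikeInExperiment-class] members.
#' @slot truth the shared [GroundTruth-class].
#' @exportClass WorkflowEnsemble
setClass("WorkflowEnsemble",
  representation(labels = "character", datasets = "list",
                 truth = "GroundTruth"))

setValidity("WorkflowEnsemble", function(object) {
  msg <- character(0)
  if (length(object@labels) != length(object@datasets)) {
    msg <- c(msg, "one label per dataset required")
  }
  if (length(object@datasets) < 1L) msg <- c(msg, "ensemble must have >= 1 member")
  if (!all(vapply(object@datasets, is, logical(1), "SpikeInExperiment"))) {
    msg <- c(msg, "all members must be SpikeInExperiment objects")
  } else if (length(object@datasets) > 1L) {
    ann <- lapply(object@datasets, function(d) {
      data.frame(sample = colnames(d), condition = colData(d)$condition)
    })
    if (!all(vapply(ann[-1], identical, logical(1), ann[[1]]))) {
      msg <- c(msg, "all members must share the same sample annotation")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpikeInExperiment", function(object) {
  sp <- table(factor(rowData(object)$species, levels = .SPECIES_LEVELS))
  cat(sprintf("SpikeInExperiment: %d proteins (%d human, %d ecoli, %d ambiguous) x %d samples\n",
              nrow(object), sp[["human"]], sp[["ecoli"]], sp[["ambiguous"]],
              ncol(object)))
  cat("conditions:", paste(sprintf("%s(%d)", names(table(colData(object)$condition)),
                                   table(colData(object)$condition)), collapse = " "), "\n")
  a <- assay(object, "log2intensity")
  cat(sprintf("missing: %.1f%% of cells\n", 100 * mean(is.na(a))))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d proteins (%d spike), pair %s vs %s\n",
              length(object@protein), sum(object@species == "ecoli"),
              object@comparedConditions[1], object@comparedConditions[2]))
})

setMethod("show", "WorkflowEnsemble", function(object) {
  cat(sprintf("WorkflowEnsemble of %d member(s): %s\n", length(object@labels),
              paste(object@labels, collapse = ", ")))
})

# ---- accessors -------------------------------------------------------------

#' Accessors for SpikeInExperiment and friends
#'
#' `proteinSpecies` returns the per-protein species label, `sampleConditions`
#' the per-sample spike-in condition, `intensities` the log2 intensity matrix
#' (`NA` = missing), `trueLog2FC` the ground-truth fold-changes,
#' `ensembleLabels`/`ensembleDatasets` the workflow ensemble members.
#'
#' @param x a [SpikeInExperiment-class], [GroundTruth-class] or
#'   [WorkflowEnsemble-class] object.
#' @return A vector, matrix or list as described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("proteinSpecies", function(x) standardGeneric("proteinSpecies"))
#' @rdname accessors
#' @export
setMethod("proteinSpecies", "SpikeInExperiment", function(x) {
  setNames(as.character(rowData(x)$species), rownames(x))
})
#' @rdname accessors
#' @export
setMethod("proteinSpecies", "GroundTruth", function(x) {
  setNames(x@species, x@protein)
})

#' @rdname accessors
#' @export
setGeneric("sampleConditions", function(x) standardGeneric("sampleConditions"))
#' @rdname accessors
#' @export
setMethod("sampleConditions", "SpikeInExperiment", function(x) {
  setNames(as.character(colData(x)$condition), colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "SpikeInExperiment", function(x) {
  assay(x, "log2intensity")
})

#' @rdname accessors
#' @export
setGeneric("trueLog2FC", function(x) standardGeneric("trueLog2FC"))
#' @rdname accessors
#' @export
setMethod("trueLog2FC", "GroundTruth", function(x) {
  setNames(x@trueLog2FC, x@protein)
})

#' @rdname accessors
#' @export
setGeneric("presentIn", function(x) standardGeneric("presentIn"))
#' @rdname accessors
#' @export
setMethod("presentIn", "GroundTruth", function(x) {
  setNames(x@presentIn, x@protein)
})

#' @rdname accessors
#' @export
setGeneric("ensembleLabels", function(x) standardGeneric("ensembleLabels"))
#' @rdname accessors
#' @export
setMethod("ensembleLabels", "WorkflowEnsemble", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("ensembleDatasets", function(x) standardGeneric("ensembleDatasets"))
#' @rdname accessors
#' @export
setMethod("ensembleDatasets", "WorkflowEnsemble", function(x) {
  setNames(x@datasets, x@labels)
})

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "WorkflowEnsemble", function(x) x@truth)
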