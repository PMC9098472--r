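#' Classify protein entry names by species suffix
#'
#' Entry names follow the Swiss-Prot convention of a `_SPECIES` suffix.
#' Compound identifiers joining several entry names with a separator are
#' classified unanimously: `human` iff every joined name carries the human
#' suffix, `ecoli` iff every name carries the E. coli suffix, `ambiguous`
#' otherwise (including mixed-species identifiers, which downstream
#' harmonization removes).
#'
#' @param entryNames character vector of (possibly compound) entry names.
#' @param suffixes named character vector mapping species to suffix.
#' @param sep separator joining compound identifiers.
#' @return Character vector in `c("human", "ecoli", "ambiguous")`.
#' @export
#' @examples
#' parseSpecies(c("ALBU_HUMAN", "DNAK_ECOLI", "ALBU_HUMAN;DNAK_ECOLI"))
parseSpecies <- function(entryNames,
                         suffixes = c(human = "_HUMAN", ecoli = "_ECOLI"),
                         sep = ";") {
  if (length(entryNames) == 0) return(character(0))
  if (any(is.na(entryNames) | !nzchar(entryNames))) {
    stop("entry names must be non-empty")
  }
  vapply(strsplit(entryNames, sep, fixed = TRUE), function(parts) {
    if (!length(parts)) return("ambiguous")
    isHuman <- endsWith(parts, suffixes[["human"]])
    isEcoli <- endsWith(parts, suffixes[["ecoli"]])
    if (all(isHuman)) "human" else if (all(isEcoli)) "ecoli" else "ambiguous"
  }, character(1))
}

#' Read a protein intensity matrix and its sample annotation
#'
#' Reads delimited text with a header row whose first column holds protein
#' entry names. Cells matching `naCodes` become missing. With
#' `scale = "raw"` values are log2-transformed after treating values <= 0 as
#' missing; with `scale = "log2"` values are stored as-is.
#'
#' @param file path to the matrix file.
#' @param annotation path to a sample-annotation table (columns `sample`,
#'   `condition`, optional logical `exclude`), or a data.frame of the same
#'   shape. Excluded samples are dropped.
#' @param sep field separator (default tab).
#' @param scale `"log2"` (default) or `"raw"`.
#' @param naCodes character values treated as missing (default empty and
#'   `"NA"`; add `"0"` for suites that zero-code missing values).
#' @param suffixes,compoundSep passed to [parseSpecies()].
#' @return A [SpikeInExperiment-class].
#' @export
readIntensityMatrix <- function(file, annotation, sep = "\t",
                                scale = c("log2", "raw"),
                                naCodes = c("", "NA"),
                                suffixes = c(human = "_HUMAN", ecoli = "_ECOLI"),
                                compoundSep = ";") {
  scale <- match.arg(scale)
  tab <- read.delim(file, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("matrix file needs a protein column plus >= 1 sample")
  proteins <- tab[[1]]
  if (anyDuplicated(proteins)) {
    stop(sprintf("duplicate protein id(s): %s",
                 paste(unique(proteins[duplicated(proteins)]), collapse = ", ")))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  vals[vals %in% naCodes] <- NA_character_
  m <- matrix(as.numeric(vals), nrow = nrow(vals),
              dimnames = list(proteins, colnames(vals)))
  if (scale == "raw") {
    m[!is.na(m) & m <= 0] <- NA_real_
    m <- log2(m)
  }

  ann <- if (is.character(annotation)) {
    read.delim(annotation, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  } else as.data.frame(annotation)
  if (!all(c("sample", "condition") %in% colnames(ann))) {
    stop("annotation needs 'sample' and 'condition' columns")
  }
  if (anyDuplicated(ann$sample)) stop("annotation: duplicate sample id(s)")
  if ("exclude" %in% colnames(ann)) {
    drop <- ann$sample[as.logical(ann$exclude) %in% TRUE]
    ann <- ann[!ann$sample %in% drop, , drop = FALSE]
    m <- m[, !colnames(m) %in% drop, drop = FALSE]
  }
  unknown <- setdiff(colnames(m), ann$sample)
  if (length(unknown)) {
    stop(sprintf("sample(s) absent from annotation: %s",
                 paste(unknown, collapse = ", ")))
  }
  cond <- setNames(ann$condition, ann$sample)[colnames(m)]
  SpikeInExperiment(m, species = parseSpecies(proteins, suffixes, compoundSep),
                    condition = cond)
}

#' Write a SpikeInExperiment (matrix + annotation) to TSV
#'
#' The matrix is written proteins-in-rows with the entry name in the first
#' column and missing cells as empty fields; the annotation holds one
#' `(sample, condition)` row per sample.
#'
#' @param x a [SpikeInExperiment-class].
#' @param matrixFile,annotationFile output paths (either may be `NULL` to
#'   skip).
#' @param sep field separator.
#' @return Invisibly, the paths written.
#' @export
writeIntensityMatrix <- function(x, matrixFile, annotationFile = NULL,
                                 sep = "\t") {
  m <- intensities(x)
  out <- data.frame(protein = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, matrixFile, sep = sep, quote = FALSE, row.names = FALSE,
              na = "")
  if (!is.null(annotationFile)) {
    ann <- data.frame(sample = colnames(x),
                      condition = sampleConditions(x))
    write.table(ann, annotationFile, sep = sep, quote = FALSE,
                row.names = FALSE)
  }
  invisible(c(matrixFile, annotationFile))
}

#' Write a ground-truth manifest to TSV
#'
#' Columns: protein, species, true_log2fc, present_in (conditions joined by
#' commas).
#'
#' @param truth a [GroundTruth-class].
#' @param file output path.
#' @param sep field separator.
#' @return Invisibly, `file`.
#' @export
writeGroundTruth <- function(truth, file, sep = "\t") {
  out <- data.frame(
    protein = truth@protein, species = truth@species,
    true_log2fc = truth@trueLog2FC,
    present_in = vapply(truth@presentIn, paste, character(1), collapse = ","))
  write.table(out, file, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Harmonize a dataset to the common analysis format
#'
#' Removes proteins whose identifier maps to both species (`ambiguous`) and
#' proteins without any reported quantitation, recording the removal counts in
#' the object metadata. Idempotent.
#'
#' @param x a [SpikeInExperiment-class].
#' @return The harmonized [SpikeInExperiment-class].
#' @export
setGeneric("harmonize", function(x) standardGeneric("harmonize"))

#' @rdname harmonize
#' @export
setMethod("harmonize", "SpikeInExperiment", function(x) {
  ambiguous <- proteinSpecies(x) == "ambiguous"
  allMissing <- rowSums(!is.na(intensities(x))) == 0
  keep <- !ambiguous & !allMissing
  if (!any(keep)) stop("no proteins left after harmonization")
  out <- x[keep, ]
  md <- metadata(out)
  md$harmonization <- list(removedAmbiguous = sum(ambiguous),
                           removedAllMissing = sum(allMissing & !ambiguous))
  metadata(out) <- md
  validObject(out)
  out
})
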