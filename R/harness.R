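#' @include AllClasses.R resample.R stats-core.R
NULL

#' GridSpec: the factorial benchmark grid
#'
#' @slot workflows named list of [SpikeInExperiment-class] datasets (e.g. the
#'   members of a [WorkflowEnsemble-class]).
#' @slot truth the shared [GroundTruth-class].
#' @slot sparsity sparsity-reduction levels to run.
#' @slot normalization normalization methods to run.
#' @slot tests statistical tests to run.
#' @slot design the [BootstrapDesign-class].
#' @slot referenceLists which reference lists to evaluate against (subset of
#'   `workflow`, `combined`, `intersection`).
#' @slot fprMax,alpha,trqnQ evaluation and preprocessing settings.
#' @exportClass GridSpec
setClass("GridSpec",
  representation(workflows = "list", truth = "GroundTruth",
                 sparsity = "character", normalization = "character",
                 tests = "character", design = "BootstrapDesign",
                 referenceLists = "character", fprMax = "numeric",
                 alpha = "numeric", trqnQ = "numeric"))

setValidity("GridSpec", function(object) {
  msg <- character(0)
  if (!length(object@workflows)) msg <- c(msg, "need >= 1 workflow dataset")
  if (!length(object@sparsity)) msg <- c(msg, "need >= 1 sparsity level")
  if (!length(object@normalization)) msg <- c(msg, "need >= 1 normalization")
  if (!length(object@tests)) msg <- c(msg, "need >= 1 test")
  if (!all(object@tests %in% .TEST_METHODS)) {
    msg <- c(msg, "unknown test method in grid")
  }
  if (!all(object@referenceLists %in% c("workflow", "combined", "intersection"))) {
    msg <- c(msg, "referenceLists must be among workflow/combined/intersection")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a benchmark grid specification
#'
#' @param workflows a [WorkflowEnsemble-class], or a named list of
#'   [SpikeInExperiment-class] datasets (then `truth` is required).
#' @param truth a [GroundTruth-class] (taken from the ensemble when omitted).
#' @param sparsity,normalization,tests option lists for the three workflow
#'   stages.
#' @param design a [BootstrapDesign-class].
#' @param referenceLists reference lists to evaluate against.
#' @param fprMax,alpha,trqnQ evaluation / preprocessing settings.
#' @return A [GridSpec-class].
#' @export
gridSpec <- function(workflows, truth = NULL,
                     sparsity = c("NoSR", "SR66", "SR90"),
                     normalization = c("unnormalized", "median", "QN", "TRQN"),
                     tests = .TEST_METHODS,
                     design = bootstrapDesign(),
                     referenceLists = c("workflow", "combined", "intersection"),
                     fprMax = 0.1, alpha = 0.05, trqnQ = 0.5) {
  if (is(workflows, "WorkflowEnsemble")) {
    truth <- groundTruth(workflows)
    workflows <- ensembleDatasets(workflows)
  }
  if (is.null(truth)) stop("truth is required when workflows is a plain list")
  if (is.null(names(workflows))) {
    names(workflows) <- sprintf("workflow%02d", seq_along(workflows))
  }
  new("GridSpec", workflows = workflows, truth = truth,
      sparsity = sparsity, normalization = normalization, tests = tests,
      design = design, referenceLists = referenceLists, fprMax = fprMax,
      alpha = alpha, trqnQ = trqnQ)
}

setMethod("show", "GridSpec", function(object) {
  cc <- countCombinations(object)
  cat(sprintf("GridSpec: %d workflows x %d SR x %d norms x %d tests = %d combinations; %d bootstrap datasets -> %s cases\n",
              length(object@workflows), length(object@sparsity),
              length(object@normalization), length(object@tests),
              cc$workflowLevel, cc$bootstrapDatasets,
              format(cc$caseLevel, big.mark = ",")))
})

#' Count the combinations a grid specification spans
#'
#' Pure arithmetic, no execution: the workflow-level count is
#' `|workflows| * |sparsity| * |normalizations| * |tests|`; the case-level
#' count multiplies by the number of bootstrap datasets.
#'
#' @param spec a [GridSpec-class].
#' @return A list with `workflowLevel`, `bootstrapDatasets`, `caseLevel`.
#' @export
countCombinations <- function(spec) {
  wl <- length(spec@workflows) * length(spec@sparsity) *
    length(spec@normalization) * length(spec@tests)
  nb <- length(spec@design@sizes) * spec@design@replicates
  list(workflowLevel = wl, bootstrapDatasets = nb, caseLevel = wl * nb)
}

# evaluation-ready outcome: proteins removed by sparsity reduction re-enter
# with p = 1 and status removed_by_sr (the spec'd coercion)
.completeOutcome <- function(outcome, removed) {
  if (!length(removed)) return(outcome)
  rbind(outcome,
        data.frame(protein = removed, p_value = 1, log2fc = NA_real_,
                   status = "removed_by_sr", stringsAsFactors = FALSE))
}

#' Run the full factorial benchmark grid
#'
#' For every bootstrap dataset and every (workflow, sparsity, normalization,
#' test) combination: draw, preprocess (sparsity reduction then
#' normalization), test, and evaluate against each requested reference list.
#' Rows are emitted in deterministic order and the whole run is reproducible
#' from the design's base seed. Per-row failures are recorded in the `status`
#' column rather than aborting the run.
#'
#' @param spec a [GridSpec-class].
#' @param done optional `data.frame` of previously completed rows (as
#'   returned by `runGrid`); their key tuples are skipped and the rows
#'   re-used, making long runs resumable.
#' @param verbose print per-bootstrap progress.
#' @return A `data.frame` with key columns (`workflow`, `sparsity`,
#'   `normalization`, `test`, `n`, `replicate`, `reference`), the
#'   [evaluateOutcome()] measures, the [dataCharacteristics()] fields and a
#'   `status` column.
#' @export
runGrid <- function(spec, done = NULL, verbose = FALSE) {
  validObject(spec)
  entries <- enumerateDesign(spec@design)
  refs <- buildReferenceLists(lapply(spec@workflows, rownames))
  doneKey <- if (!is.null(done)) {
    with(done, paste(workflow, sparsity, normalization, test, n, replicate,
                     reference, sep = "\r"))
  } else character(0)

  rows <- list()
  for (e in seq_len(nrow(entries))) {
    n <- entries$n[e]
    repl <- entries$replicate[e]
    if (verbose) message(sprintf("bootstrap n=%d replicate=%d", n, repl))
    for (w in names(spec@workflows)) {
      boot <- drawBootstrap(spec@workflows[[w]], n = n,
                            seed = deriveSeed(entries$seed[e], "draw", w),
                            pair = spec@design@pair)
      chars <- dataCharacteristics(boot$matrix, boot$groups)
      for (sr in spec@sparsity) {
        red <- sparsityReduce(boot$matrix, sr)
        for (nm in spec@normalization) {
          prep <- tryCatch(
            normalizeIntensities(red$matrix, nm, q = spec@trqnQ),
            error = function(e) NULL)
          for (ts in spec@tests) {
            key <- paste(w, sr, nm, ts, n, repl, sep = "\r")
            if (length(doneKey) && any(startsWith(doneKey, paste0(key, "\r")))) {
              rows[[length(rows) + 1L]] <-
                done[startsWith(doneKey, paste0(key, "\r")), , drop = FALSE]
              next
            }
            base <- data.frame(workflow = w, sparsity = sr,
                               normalization = nm, test = ts, n = n,
                               replicate = repl, stringsAsFactors = FALSE)
            if (is.null(prep)) {
              for (rl in spec@referenceLists) {
                rows[[length(rows) + 1L]] <- cbind(
                  base, reference = rl, pauc = NA_real_,
                  sensitivity = NA_real_, rmse = NA_real_,
                  n_excluded = NA_integer_, tp = NA_integer_,
                  fp = NA_integer_, tn = NA_integer_, fn = NA_integer_,
                  chars, status = "preprocessing_empty")
              }
              next
            }
            outcome <- tryCatch(
              runTest(prep, boot$groups, ts,
                      seed = deriveSeed(entries$seed[e], "test", w, ts)),
              error = function(e) NULL)
            if (is.null(outcome)) {
              for (rl in spec@referenceLists) {
                rows[[length(rows) + 1L]] <- cbind(
                  base, reference = rl, pauc = NA_real_,
                  sensitivity = NA_real_, rmse = NA_real_,
                  n_excluded = NA_integer_, tp = NA_integer_,
                  fp = NA_integer_, tn = NA_integer_, fn = NA_integer_,
                  chars, status = "test_failure")
              }
              next
            }
            outcome <- .completeOutcome(outcome, red$removed)
            for (rl in spec@referenceLists) {
              reference <- switch(rl,
                workflow = refs$workflow[[w]],
                combined = refs$combined,
                intersection = refs$intersection)
              ev <- tryCatch(
                evaluateOutcome(outcome, spec@truth, reference,
                                fprMax = spec@fprMax, alpha = spec@alpha),
                error = function(e) NULL)
              rows[[length(rows) + 1L]] <- if (is.null(ev)) {
                cbind(base, reference = rl, pauc = NA_real_,
                      sensitivity = NA_real_, rmse = NA_real_,
                      n_excluded = NA_integer_, tp = NA_integer_,
                      fp = NA_integer_, tn = NA_integer_, fn = NA_integer_,
                      chars, status = "evaluation_failure")
              } else {
                cbind(base, reference = rl, ev, chars, status = "ok")
              }
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ord <- with(out, order(workflow, sparsity, normalization, test, n,
                         replicate, reference))
  out[ord, , drop = FALSE]
}

#' Summarize grid results
#'
#' Per group (default: test x reference list): median and quartiles of pAUC,
#' sensitivity and RMSE, plus a flag on the best option (maximal median pAUC)
#' within each reference list.
#'
#' @param rows `data.frame` from [runGrid()].
#' @param by key columns to group on (default `c("test", "reference")`).
#' @return A `data.frame`, one row per group, sorted by median pAUC within
#'   reference list.
#' @export
summarizeGrid <- function(rows, by = c("test", "reference")) {
  if (!nrow(rows)) stop("empty result table")
  rows <- rows[rows$status == "ok" & !is.na(rows$pauc), , drop = FALSE]
  if (!nrow(rows)) stop("no successful rows to summarize")
  key <- interaction(rows[by], drop = TRUE, sep = "\r")
  agg <- do.call(rbind, lapply(split(rows, key), function(g) {
    cbind(g[1, by, drop = FALSE],
          data.frame(
            n_rows = nrow(g),
            pauc_median = median(g$pauc), pauc_q1 = quantile(g$pauc, 0.25),
            pauc_q3 = quantile(g$pauc, 0.75),
            sensitivity_median = median(g$sensitivity, na.rm = TRUE),
            rmse_median = median(g$rmse, na.rm = TRUE)))
  }))
  rownames(agg) <- NULL
  if ("reference" %in% by) {
    agg$best <- FALSE
    for (rl in unique(agg$reference)) {
      i <- which(agg$reference == rl)
      agg$best[i[which.max(agg$pauc_median[i])]] <- TRUE
    }
    agg <- agg[order(agg$reference, -agg$pauc_median), , drop = FALSE]
  } else {
    agg$best <- seq_len(nrow(agg)) == which.max(agg$pauc_median)
    agg <- agg[order(-agg$pauc_median), , drop = FALSE]
  }
  rownames(agg) <- NULL
  agg
}
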