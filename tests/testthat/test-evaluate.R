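test_that("reference lists implement the count-floor intersection rule", {
  # 17 workflows at threshold 0.8 -> membership count >= 14
  refs17 <- buildReferenceLists(c(
    replicate(14, c("A", "B"), simplify = FALSE),
    replicate(3, list("B"))), threshold = 0.8)
  expect_equal(refs17$minCount, 14)
  expect_setequal(refs17$intersection, c("A", "B"))

  refs <- buildReferenceLists(list(w1 = c("A", "B"), w2 = c("B", "C"),
                                   w3 = "B"), threshold = 0.8)
  expect_identical(refs$intersection, "B")
  expect_setequal(refs$combined, c("A", "B", "C"))

  one <- buildReferenceLists(list(w = c("X", "Y")))
  expect_setequal(one$combined, c("X", "Y"))
  expect_setequal(one$intersection, c("X", "Y"))
  expect_error(buildReferenceLists(list()), "empty")
})

test_that("ROC construction honors perfect separation, caps, and ties", {
  proteins <- c("E1", "E2", "H1", "H2")
  truth <- handTruth(proteins, c("ecoli", "ecoli", "human", "human"))
  perfect <- data.frame(protein = proteins, p_value = c(0, 0, 1, 1),
                        log2fc = 0, status = "tested")
  curve <- rocPoints(perfect, truth, proteins)
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))
  expect_equal(pauc(curve), 100)

  # half the reference spike proteins absent from the outcome cap the TPR
  half <- data.frame(protein = c("E1", "H1", "H2"), p_value = c(0, 1, 1),
                     log2fc = 0, status = "tested")
  curveHalf <- rocPoints(half, truth, proteins)
  expect_equal(max(curveHalf$tpr), 0.5)

  # tied p-values advance TP and FP jointly in one vertex
  tied <- data.frame(protein = proteins, p_value = c(0.01, 0.2, 0.2, 0.9),
                     log2fc = 0, status = "tested")
  curveTied <- rocPoints(tied, truth, proteins)
  expect_equal(curveTied$fpr, c(0, 0, 0.5, 1))
  expect_equal(curveTied$tpr, c(0, 0.5, 1, 1))

  expect_error(rocPoints(perfect, truth, c("E1", "E2")), "both species")
})

test_that("scaled pAUC has the right ceiling, diagonal value and boundary interpolation", {
  perfect <- data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  expect_equal(pauc(perfect), 100)
  diagonal <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
  expect_equal(pauc(diagonal), 5)         # 0.1^2/2 scaled by 100/0.1
  expect_equal(pauc(diagonal, fprMax = 1), 50)
  expect_error(pauc(diagonal, fprMax = 0), "fprMax")
  expect_error(pauc(diagonal, fprMax = 1.5), "fprMax")
  # terminal FPR below the ceiling: horizontal extension at terminal TPR
  short <- data.frame(fpr = c(0, 0.05), tpr = c(0, 0.8))
  expect_equal(pauc(short), 100 * (0.05 * 0.4 + 0.05 * 0.8) / 0.1)
})

test_that("scaled pAUC agrees with the brute-force threshold oracle", {
  set.seed(31)
  for (i in 1:25) {
    nP <- sample(3:40, 1)
    nN <- sample(3:60, 1)
    proteins <- c(sprintf("E%02d", seq_len(nP)), sprintf("H%02d", seq_len(nN)))
    species <- rep(c("ecoli", "human"), c(nP, nN))
    truth <- handTruth(proteins, species)
    p <- sample(round(runif(20), 3), nP + nN, replace = TRUE)  # forces ties
    if (i %% 3 == 0) p[sample(length(p), 2)] <- NA             # missing -> 1
    outcome <- data.frame(protein = proteins, p_value = p, log2fc = 0,
                          status = "tested")
    mine <- pauc(rocPoints(outcome, truth, proteins))
    oracle <- bruteForcePauc(p, species == "ecoli", nP, nN)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("pAUC is invariant to monotone p transforms and penalized by added negatives", {
  proteins <- c(sprintf("E%d", 1:5), sprintf("H%d", 1:10))
  species <- rep(c("ecoli", "human"), c(5, 10))
  truth <- handTruth(proteins, species)
  set.seed(2)
  p <- runif(15)
  out <- data.frame(protein = proteins, p_value = p, log2fc = 0,
                    status = "tested")
  outT <- transform(out, p_value = plogis(5 * (p - 0.5)))  # strictly monotone
  expect_equal(pauc(rocPoints(out, truth, proteins)),
               pauc(rocPoints(outT, truth, proteins)), tolerance = 1e-10)

  # on a fixed reference containing an extra negative, reporting it with
  # p = 1 (instead of not at all) can never increase the pAUC
  proteins2 <- c(proteins, "H11")
  truth2 <- handTruth(proteins2, c(species, "human"))
  out2 <- rbind(out, data.frame(protein = "H11", p_value = 1, log2fc = 0,
                                status = "tested"))
  expect_lte(pauc(rocPoints(out2, truth2, proteins2)),
             pauc(rocPoints(out, truth2, proteins2)) + 1e-10)
})

test_that("sensitivity counts absent spike proteins in the denominator only", {
  proteins <- c("E1", "E2", "E3", "E4", "H1")
  truth <- handTruth(proteins, c(rep("ecoli", 4), "human"))
  out <- data.frame(protein = c("E1", "E2", "E3", "H1"),
                    p_value = c(0.01, 0.02, 0.2, 0.5), log2fc = 0,
                    status = "tested")
  expect_equal(sensitivityAt(out, truth, proteins), 2 / 4)
  allLow <- data.frame(protein = proteins, p_value = 0, log2fc = 0,
                       status = "tested")
  expect_equal(sensitivityAt(allLow, truth, proteins), 1)
  allHigh <- transform(allLow, p_value = 1)
  expect_equal(sensitivityAt(allHigh, truth, proteins), 0)
  expect_error(sensitivityAt(out, truth, c("H1", "H1x")), "ground truth")
})

test_that("RMSE follows the truth constants and exclusion rules", {
  proteins <- c("E1", "H1")
  truth <- handTruth(proteins, c("ecoli", "human"))
  exact <- data.frame(protein = proteins, p_value = 0.5,
                      log2fc = c(1.11, 0), status = "tested")
  expect_equal(rmseLog2FC(exact, truth, proteins)$rmse, 0)

  single <- data.frame(protein = "E1", p_value = 0.5, log2fc = 0,
                       status = "tested")
  expect_equal(rmseLog2FC(single, truth, "E1")$rmse, 1.11)

  both <- data.frame(protein = proteins, p_value = 0.5,
                     log2fc = c(1.5, 0.5), status = "tested")
  r <- rmseLog2FC(both, truth, proteins)
  expect_equal(r$rmse, sqrt((0.25 + 0.1521) / 2))
  expect_equal(r$nExcluded, 0)

  withNA <- data.frame(protein = proteins, p_value = 0.5,
                       log2fc = c(NA, 0.5), status = "insufficient_data")
  expect_equal(rmseLog2FC(withNA, truth, proteins)$nExcluded, 1)
  noneDefined <- transform(withNA, log2fc = NA_real_)
  expect_error(rmseLog2FC(noneDefined, truth, proteins), "defined estimate")
})

test_that("sensitivity on nested references respects the cap mechanism", {
  # intersection = combined minus two spike proteins the workflow never saw
  combined <- c(sprintf("E%d", 1:4), sprintf("H%d", 1:4))
  intersection <- c(sprintf("E%d", 1:2), sprintf("H%d", 1:4))
  truth <- handTruth(combined, rep(c("ecoli", "human"), each = 4))
  out <- data.frame(protein = intersection, p_value = c(0.01, 0.01, rep(0.5, 4)),
                    log2fc = 0, status = "tested")
  expect_gte(sensitivityAt(out, truth, intersection),
             sensitivityAt(out, truth, combined))
})

test_that("missingness profiles count fractions and flag undefined correlations", {
  m <- matrix(c(20, NA, 18, 19, 21, 22, NA, 23, 17, 18, 19, 20), 3, 4,
              byrow = TRUE,
              dimnames = list(c("A_HUMAN", "B_HUMAN", "C_ECOLI"),
                              paste0("s", 1:4)))
  se <- SpikeInExperiment(m, condition = rep(c("r1:25", "r1:12"), 2))
  prof <- missingnessProfile(se)
  expect_equal(prof$proteins$missing_fraction, c(0.25, 0.25, 0))
  expect_equal(prof$samples$missing_fraction, c(0, 1 / 3, 1 / 3, 0))

  complete <- SpikeInExperiment(
    matrix(20, 2, 2, dimnames = list(c("A_HUMAN", "B_ECOLI"), c("s1", "s2"))),
    condition = c("a", "b"))
  profC <- missingnessProfile(complete)
  expect_false(any(profC$correlations$defined))
})
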