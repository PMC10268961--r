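test_that("confusion metrics follow their definitions", {
  m <- confusionMetrics(90, 0, 0, 10)
  expect_equal(m$tpr, 0.9)
  m2 <- confusionMetrics(5, 0, 100, 5)
  expect_identical(m2$fpr, 0)
  expect_identical(m2$tnr, 1)
  m3 <- confusionMetrics(4, 1, 95, 0)
  expect_equal(m3$mcc, 0.8897565, tolerance = 1e-6)
  # zero-denominator convention is flagged
  m4 <- confusionMetrics(0, 0, 10, 0)
  expect_identical(m4$mcc, 0)
  expect_true("mcc" %in% m4$zero_denominator)
  expect_error(confusionMetrics(-1, 0, 0, 2), "non-negative")
})

test_that("rocAuc equals brute-force pairwise concordance", {
  expect_equal(rocAuc(c(3, 4, 5, 0, 1, 2), c(1, 1, 1, 0, 0, 0)), 1.0)
  expect_equal(rocAuc(rep(1, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(rocAuc(1:5, rep(1, 5)), "both classes")
  set.seed(53)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    labels <- sample(c(0L, 1L), n, replace = TRUE, prob = c(0.7, 0.3))
    if (length(unique(labels)) < 2) next
    scores <- sample(seq(-1, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    expect_equal(rocAuc(scores, labels), oracleAuc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("cross-validation recovers planted structure and is seeded", {
  fx <- generatePlantedFixture(30, 300, 10, 1, 0, seed = 61)
  folds <- assignFolds(setNames(fx@labels, molIds(fx)), k = 5,
                       loo_threshold = 20, seed = 61)
  cfg <- iseConfig(n_bins = 2, seed = 61)
  rep1 <- crossValidate(fx@table, fx@labels, folds, cfg)
  expect_equal(rep1@meanTopFilterMcc, 1.0)
  expect_gte(rep1@auc, 0.99)
  expect_identical(nrow(rep1@perFold), 5L)
  rep2 <- crossValidate(fx@table, fx@labels, folds, cfg)
  expect_identical(rep1@perFold, rep2@perFold)
  expect_identical(rep1@auc, rep2@auc)
})

test_that("LOO cross-validation runs one cycle per active", {
  fx <- generatePlantedFixture(11, 110, 10, 1, 0, seed = 67)
  folds <- assignFolds(setNames(fx@labels, molIds(fx)), k = 5, seed = 67)
  expect_identical(folds@scheme, "loo")
  rep <- crossValidate(fx@table, fx@labels, folds,
                       iseConfig(n_bins = 2, seed = 67))
  expect_identical(nrow(rep@perFold), 11L)
  expect_equal(rep@meanTopFilterMcc, 1.0)
})

test_that("Y-randomization converges to the predicted-positive density", {
  m <- matrix(0, 20, 10, dimnames = list(sprintf("d%02d", 1:20),
                                         sprintf("t%02d", 1:10)))
  allOnes <- interactionMatrix(m + 1, "predicted")
  yr1 <- yRandomization(allOnes, 30, n_reps = 5, seed = 1)
  expect_identical(yr1$mean_success, 1)
  allZero <- interactionMatrix(m, "predicted")
  expect_identical(yRandomization(allZero, 30, 5, seed = 1)$mean_success, 0)
  # density p: mean over many reps within 3 standard errors of p
  set.seed(3)
  m2 <- m; m2[sample(length(m2), 40)] <- 1  # p = 0.2
  pred <- interactionMatrix(m2, "predicted")
  yr <- yRandomization(pred, 25, n_reps = 10000, seed = 5)
  se <- yr$sd_success / sqrt(10000)
  expect_lt(abs(yr$mean_success - 0.2), 3 * se + 1e-12)
  expect_error(yRandomization(pred, 25, 0), "n_reps")
  expect_error(yRandomization(pred, 1e6, 5), "cell count")
})

test_that("matrix comparison counts covered interactions", {
  dn <- list(sprintf("d%d", 1:4), sprintf("t%d", 1:3))
  rep <- matrix(c(1, 0, 0, 1, 1, 0, 0, 0, 1, 0, 1, 0), 4, 3,
                dimnames = dn)
  predAll <- interactionMatrix(rep, "predicted")
  cmp <- compareMatrices(predAll, interactionMatrix(rep, "reported"))
  expect_equal(cmp$overall_success_pct, 100)
  predNone <- interactionMatrix(rep * 0, "predicted")
  expect_equal(compareMatrices(predNone,
               interactionMatrix(rep, "reported"))$overall_success_pct, 0)
  # 3 of 5 reported covered -> 60%
  pred <- rep; pred[1, 1] <- 0; pred[4, 1] <- 0
  cmp3 <- compareMatrices(interactionMatrix(pred, "predicted"),
                          interactionMatrix(rep, "reported"))
  expect_equal(cmp3$overall_success_pct, 100 * 3 / 5)
  # invariant under simultaneous row/column permutation
  pr <- sample(4); pc <- sample(3)
  cmpP <- compareMatrices(
    interactionMatrix(pred[pr, pc], "predicted"),
    interactionMatrix(rep[pr, pc], "reported"))
  expect_equal(cmpP$overall_success_pct, cmp3$overall_success_pct)
  expect_error(compareMatrices(interactionMatrix(rep[1:3, ], "predicted"),
                               interactionMatrix(rep, "reported")),
               "axes")
})

test_that("diversity report matches brute-force pairwise means", {
  f1 <- new("Fingerprint", bits = c(1, 2, 3, 4))
  f2 <- new("Fingerprint", bits = c(3, 4, 5, 6))
  f3 <- new("Fingerprint", bits = c(1, 2, 3, 4))
  rep <- diversityReport(list(f1, f2, f3), list(f1, f2))
  expect_equal(rep$tc_actives,
               mean(c(oracleTanimoto(1:4, 3:6), 1,
                      oracleTanimoto(3:6, 1:4))))
  expect_equal(rep$tc_top_internal, oracleTanimoto(1:4, 3:6))
  expect_equal(rep$tc_top_vs_actives, 1)  # both tops have an exact active
  # all-identical set -> 1, not diverse
  same <- diversityReport(list(f1, f3), list(f1, f3))
  expect_equal(same$tc_actives, 1)
  expect_false(same$diverse_actives)
  # threshold behaviour at 0.69
  expect_true(diversityReport(list(f1, f2), list(f1, f2),
                              threshold = 0.7)$tc_actives < 0.7)
  expect_warning(d1 <- diversityReport(list(f1), list(f1, f2)),
                 "undefined")
  expect_true(is.na(d1$tc_actives))
})

test_that("descriptor family occurrence sums to 100", {
  dn <- c("pc_max", "pc_min", "pc_sd", "adm_wiener", "adm_radius")
  descs <- matrix(rep(dn, 4), ncol = 5, byrow = TRUE)
  fs <- new("FilterSet", descriptors = descs,
            lows = matrix(0, 4, 5), highs = matrix(1, 4, 5),
            tp = rep(1L, 4), fp = rep(0L, 4), tn = rep(1L, 4),
            fn = rep(0L, 4), mcc = rep(0.5, 4))
  m <- new("IseModel", filters = fs, weightsScheme = "unit",
           config = unclass(iseConfig()), descriptors = dn)
  occ <- descriptorFamilyOccurrence(m)
  expect_equal(sum(occ$pct), 100, tolerance = 1e-9)
  # 3:2 split in every filter -> 60/40
  expect_equal(occ$pct[occ$family == "partial_charge"], 60)
  expect_equal(occ$pct[occ$family == "adjacency_distance_matrix"], 40)
  # unmapped descriptor errors
  m2 <- m
  m2@filters@descriptors[1, 1] <- "mystery"
  expect_error(descriptorFamilyOccurrence(m2), "mystery")
})
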