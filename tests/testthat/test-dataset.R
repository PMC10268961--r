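fixturePath <- function() {
  system.file("extdata", "activity_records_synthetic.csv",
              package = "isescreen", mustWork = TRUE)
}

test_that("curation applies the exclusion rules in order, fully audited", {
  rec <- readActivityCsv(fixturePath())
  expect_identical(nrow(rec), 20L)
  out <- curateActives(rec, exclusion_list = "M12")
  counts <- table(out$audit$rule)
  expect_identical(unname(counts["flagged_comment"]), 2L)
  expect_identical(unname(counts["approximate_qualifier"]), 3L)
  expect_identical(unname(counts["weak_activity"]), 2L)
  expect_identical(unname(counts["low_confidence"]), 2L)
  expect_identical(unname(counts["excluded_id"]), 1L)
  expect_identical(unname(counts["duplicate_collapsed"]), 2L)
  expect_identical(unname(counts["structural_alert"]), 2L)
  # exhaustive audit: kept + dropped = input, one rule per dropped record
  expect_identical(nrow(out$kept) + nrow(out$audit), nrow(rec))
  expect_setequal(out$kept$molecule_id,
                  c("M01", "M02", "M13", "M14", "M15", "M18"))
  # worst (largest) duplicate value kept
  expect_equal(out$kept$value_nM[out$kept$molecule_id == "M14"], 50)
  expect_equal(out$kept$value_nM[out$kept$molecule_id == "M15"], 25)
})

test_that("curation edge cases behave as specified", {
  rec <- readActivityCsv(fixturePath())
  # confidence filter is strictly 'above 7'
  out <- curateActives(rec, check_alerts = FALSE)
  expect_false("M10" %in% out$kept$molecule_id)
  # 150 uM record dropped by the 100 uM rule
  expect_true("M08" %in%
                out$audit$molecule_id[out$audit$rule == "weak_activity"])
  # optional highly-active threshold
  hi <- curateActives(rec, highly_active_nM = 20, check_alerts = FALSE)
  expect_true(all(hi$kept$value_nM <= 20))
  # empty survivor set signals insufficient actives
  expect_error(curateActives(rec[rec$qualifier == ">", , drop = FALSE]),
               class = "iseInsufficientActives")
})

test_that("the applicability domain uses per-property mean and sample SD", {
  props <- data.frame(MW = c(390, 410), clogP = c(2, 4), HBA = c(4, 6),
                      HBD = c(1, 3))
  ad <- fitApplicabilityDomain(props)
  expect_equal(ad@stats["mean", "MW"], 400)
  expect_equal(ad@stats["sd", "MW"], sd(c(390, 410)))
  # identical actives: SD 0, the box degenerates to a point
  same <- fitApplicabilityDomain(props[c(1, 1), ])
  expect_identical(unname(same@stats["sd", "MW"]), 0)
  expect_true(inApplicabilityDomain(props[1, ], same))
  expect_false(inApplicabilityDomain(props[2, ], same))
  expect_error(fitApplicabilityDomain(props[1, , drop = FALSE]),
               "at least two")
  expect_error(fitApplicabilityDomain(props[, -1]), "MW")
})

test_that("decoy sampling respects the +/- 2 SD box and the ratio", {
  set.seed(71)
  actives <- data.frame(MW = rnorm(20, 350, 30), clogP = rnorm(20, 3, 0.5),
                        HBA = round(runif(20, 2, 8)),
                        HBD = round(runif(20, 0, 4)))
  ad <- fitApplicabilityDomain(actives)
  pool <- data.frame(id = sprintf("Z%05d", 1:20000),
                     smiles = "C",
                     MW = runif(20000, 100, 700),
                     clogP = runif(20000, -2, 8),
                     HBA = round(runif(20000, 0, 14)),
                     HBD = round(runif(20000, 0, 8)))
  dec <- sampleDecoys(pool, ad, n_actives = 20, ratio = 10, seed = 7)
  expect_identical(nrow(dec), 200L)
  expect_false(attr(dec, "shortfall"))
  expect_true(all(inApplicabilityDomain(dec, ad)))
  expect_identical(anyDuplicated(dec$id), 0L)
  # reproducible under the seed
  dec2 <- sampleDecoys(pool, ad, n_actives = 20, ratio = 10, seed = 7)
  expect_identical(dec$id, dec2$id)
  # shortfall returns all eligible with a warning flag
  expect_warning(
    short <- sampleDecoys(pool[1:50, ], ad, n_actives = 20, ratio = 100,
                          seed = 7),
    "shortfall")
  expect_true(attr(short, "shortfall"))
  expect_true(all(inApplicabilityDomain(short, ad)))
})

test_that("fold assignment stratifies both classes within one molecule", {
  labels <- setNames(rep(c(1L, 0L), c(100, 1000)),
                     sprintf("m%04d", 1:1100))
  fa <- assignFolds(labels, k = 5, seed = 11)
  expect_identical(fa@scheme, "kfold")
  expect_setequal(names(fa@folds), names(labels))
  aCounts <- table(fa@folds[names(labels)[labels == 1]])
  dCounts <- table(fa@folds[names(labels)[labels == 0]])
  expect_identical(as.integer(aCounts), rep(20L, 5))
  expect_identical(as.integer(dCounts), rep(200L, 5))
  # uneven classes stay within one molecule of exact stratification
  labels2 <- setNames(rep(c(1L, 0L), c(23, 101)), sprintf("x%03d", 1:124))
  fa2 <- assignFolds(labels2, k = 5, seed = 3)
  a2 <- table(fa2@folds[names(labels2)[labels2 == 1]])
  expect_lte(max(a2) - min(a2), 1)
  # folds partition the learning set
  expect_identical(sort(names(fa2@folds)), sort(names(labels2)))
})

test_that("small active sets trigger LOO; bad k errors", {
  labels <- setNames(rep(c(1L, 0L), c(11, 110)), sprintf("m%03d", 1:121))
  fa <- assignFolds(labels, k = 5, loo_threshold = 20, seed = 5)
  expect_identical(fa@scheme, "loo")
  expect_identical(length(unique(fa@folds)), 11L)
  expect_error(assignFolds(labels, k = 1), "at least 2")
  big <- setNames(rep(c(1L, 0L), c(25, 50)), sprintf("y%03d", 1:75))
  expect_error(assignFolds(big, k = 30, loo_threshold = 10), "exceeds")
})

test_that("learning sets enforce id disjointness and the ratio contract", {
  actives <- data.frame(id = c("a1", "a2"), smiles = c("C", "CC"))
  decoys <- data.frame(id = sprintf("d%d", 1:4),
                       smiles = rep("CCC", 4))
  ls <- learningSet(actives, decoys, ratio = 2)
  expect_s4_class(ls, "LearningSet")
  expect_error(new("LearningSet", actives = actives,
                   decoys = rbind(decoys[1:3, ],
                                  data.frame(id = "a1", smiles = "C")),
                   ratio = 2L, provenance = list()),
               "disjoint")
  # shortfall must be flagged
  short <- learningSet(actives, decoys[1:3, ], ratio = 2)
  expect_true(short@provenance$shortfall)
})
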