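makeToyModel <- function(descs, lows, highs, mcc = NULL, scheme = "unit") {
  n <- nrow(descs)
  if (is.null(mcc)) mcc <- rep(0.5, n)
  fs <- new("FilterSet", descriptors = descs, lows = lows, highs = highs,
            tp = rep(1L, n), fp = rep(0L, n), tn = rep(1L, n),
            fn = rep(0L, n), mcc = sort(mcc, decreasing = TRUE))
  new("IseModel", filters = fs, weightsScheme = scheme,
      config = unclass(iseConfig()),
      descriptors = sort(unique(as.vector(descs))))
}

test_that("the screening index honours the [-1, +1] contract", {
  dn <- sprintf("D%02d", 1:5)
  descs <- matrix(rep(dn, 4), ncol = 5, byrow = TRUE)
  X <- matrix(runif(50, 0, 100), ncol = 5, dimnames = list(NULL, dn))
  # ranges covering the whole support: every molecule passes every filter
  mAll <- makeToyModel(descs, matrix(-1e9, 4, 5), matrix(1e9, 4, 5))
  scAll <- screenLibrary(mAll, X)
  expect_true(all(scAll$index == 1))
  expect_true(all(scAll$n_filters_passed == 4L))
  # empty ranges: every molecule fails every filter
  mNone <- makeToyModel(descs, matrix(1e9, 4, 5), matrix(1e9, 4, 5))
  expect_true(all(screenLibrary(mNone, X)$index == -1))
  # 3 of 4 filters passed, unit weights -> (3 - 1) / 4 = 0.5
  lows <- matrix(-1e9, 4, 5); highs <- matrix(1e9, 4, 5)
  lows[4, ] <- 1e9
  m34 <- makeToyModel(descs, lows, highs)
  sc <- scoreMolecule(m34, setNames(runif(5, 0, 100), dn))
  expect_identical(sc$index, 0.5)
  expect_identical(sc$n_filters_passed, 3L)
  # missing descriptor fails hard, naming it
  expect_error(screenLibrary(mAll, X[, 1:4, drop = FALSE]), "D05")
})

test_that("unit-weight index equals (passes - fails)/n exactly", {
  set.seed(31)
  dn <- sprintf("D%02d", 1:8)
  X <- matrix(runif(200 * 8, 0, 100), ncol = 8, dimnames = list(NULL, dn))
  descs <- t(replicate(12, sample(dn, 5)))
  lows <- matrix(runif(60, 0, 70), 12, 5)
  highs <- lows + matrix(runif(60, 10, 50), 12, 5)
  m <- makeToyModel(descs, lows, highs)
  sc <- screenLibrary(m, X)
  expect_true(all(sc$index >= -1 & sc$index <= 1))
  expect_identical(sc$index,
                   (2 * sc$n_filters_passed - 12) / 12)
  # independent per-molecule check on a subsample
  ids <- sprintf("M%06d", seq_len(nrow(X)))
  for (i in sample(nrow(X), 20)) {
    passes <- sum(vapply(seq_len(12), function(f)
      all(X[i, descs[f, ]] >= lows[f, ] & X[i, descs[f, ]] <= highs[f, ]),
      logical(1)))
    expect_identical(sc$n_filters_passed[sc$molecule_id == ids[i]], passes)
  }
})

test_that("adding a passed filter never lowers a unit-weight index", {
  set.seed(33)
  dn <- sprintf("D%02d", 1:6)
  x <- setNames(runif(6, 0, 100), dn)
  for (rep in 1:20) {
    n <- sample(2:8, 1)
    descs <- t(replicate(n, sample(dn, 5)))
    lows <- matrix(runif(5 * n, 0, 60), n, 5)
    highs <- lows + matrix(runif(5 * n, 10, 60), n, 5)
    m <- makeToyModel(descs, lows, highs)
    idx0 <- scoreMolecule(m, x)$index
    # append one filter the molecule passes (full-support ranges)
    m2 <- makeToyModel(rbind(descs, descs[1, , drop = FALSE]),
                       rbind(lows, rep(-1e9, 5)),
                       rbind(highs, rep(1e9, 5)))
    expect_gte(scoreMolecule(m2, x)$index, idx0)
  }
})

test_that("mcc and fscore weighting reweight but preserve bounds", {
  dn <- sprintf("D%02d", 1:5)
  descs <- matrix(rep(dn, 3), ncol = 5, byrow = TRUE)
  lows <- matrix(-1e9, 3, 5); highs <- matrix(1e9, 3, 5)
  lows[3, ] <- 1e9
  fs <- new("FilterSet", descriptors = descs, lows = lows, highs = highs,
            tp = c(9L, 8L, 5L), fp = c(0L, 2L, 5L), tn = c(10L, 8L, 5L),
            fn = c(1L, 2L, 5L), mcc = c(0.9, 0.6, 0.0))
  for (scheme in c("mcc", "fscore")) {
    m <- new("IseModel", filters = fs, weightsScheme = scheme,
             config = unclass(iseConfig()), descriptors = dn)
    sc <- scoreMolecule(m, setNames(rep(0, 5), dn))
    w <- filterWeights(m)
    expect_equal(sc$index, (w[1] + w[2] - w[3]) / sum(w))
    expect_true(abs(sc$index) <= 1)
  }
})

test_that("screenLibrary returns a ranked permutation of the input", {
  fx <- generatePlantedFixture(20, 80, 10, 1, 0, seed = 41)
  m <- runIse(fx@table, fx@labels, iseConfig(n_bins = 2, seed = 41))
  sc <- screenLibrary(m, fx@table)
  expect_setequal(sc$molecule_id, molIds(fx))
  expect_identical(sc$rank, seq_len(nrow(sc)))
  expect_false(is.unsorted(-sc$index))
  # planted actives outscore decoys on average
  act <- grepl("^ACT", sc$molecule_id)
  expect_gt(mean(sc$index[act]), mean(sc$index[!act]))
  # duplicated molecule gets an identical index
  X2 <- descValues(fx@table)[c(1, 1, 50), ]
  rownames(X2) <- c("a", "b", "c")
  sc2 <- screenLibrary(m, X2)
  expect_identical(sc2$index[sc2$molecule_id == "a"],
                   sc2$index[sc2$molecule_id == "b"])
  # empty library
  expect_identical(nrow(screenLibrary(m, descValues(fx@table)[0, ])), 0L)
})

test_that("enrichment factor matches its definition and edge cases", {
  # 10 actives in 1000; top-100 holds 8 -> EF = 8
  lab <- c(rep(1, 8), rep(0, 92), rep(1, 2), rep(0, 898))
  expect_equal(enrichmentFactor(lab, 100), 8.0)
  # top-10 holds all 10 of 1000 -> EF = 100
  lab2 <- c(rep(1, 10), rep(0, 990))
  expect_equal(enrichmentFactor(lab2, 10), 100)
  # selecting the whole library gives exactly 1
  expect_identical(enrichmentFactor(lab2, length(lab2)), 1)
  expect_error(enrichmentFactor(rep(0, 10), 5), class = "iseNoPositives")
  set.seed(47)
  for (i in 1:50) {
    lab3 <- sample(c(rep(1L, 7), rep(0L, 43)))
    n <- sample(50, 1)
    expect_equal(enrichmentFactor(lab3, n), oracleEf(lab3, n),
                 tolerance = 1e-12)
  }
})

test_that("chooseCutoff reports the confusion grid and recommends", {
  scores <- c(0.9, 0.8, 0.75, 0.2, -0.1, -0.5)
  labels <- c(1, 1, 1, 0, 0, 0)
  tab <- chooseCutoff(scores, labels)
  expect_true(all(c(0, 0.7) %in% tab$cutoff))
  expect_identical(tab$TP[tab$cutoff == -1], 3L)
  expect_identical(tab$n_selected[tab$cutoff == 1], 0L)
  # perfect separation: infinite TP/FP between the classes
  expect_identical(tab$tp_fp_ratio[tab$cutoff == 0.5], Inf)
  # highest cutoff with maximal TP/FP keeping at least one TP
  expect_equal(attr(tab, "recommended"), 0.8)
  # requiring all three actives pins the recommendation below their scores
  tab3 <- chooseCutoff(scores, labels, min_tp = 3)
  expect_equal(attr(tab3, "recommended"), 0.7)
  expect_error(chooseCutoff(scores, labels, cutoffs = numeric()),
               "non-empty")
})
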