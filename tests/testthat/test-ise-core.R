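test_that("range catalog builds quantile-bin unions with 1D scores", {
  pm <- makePlantedMatrix(seed = 3)
  cat3 <- buildRangeCatalog(pm$X, pm$labels, n_bins = 3)
  # n_bins bins -> n_bins (n_bins + 1) / 2 contiguous-union candidates
  expect_true(all(vapply(cat3@ranges, nrow, integer(1)) == 6L))
  expect_identical(cat3@descriptors, sort(colnames(pm$X), method = "radix"))
  for (rt in cat3@ranges) {
    expect_true(all(rt$low <= rt$high))
    expect_false(is.unsorted(rt$low))
  }
  # perfectly separated descriptor: one candidate reaches MCC 1
  X <- pm$X
  X[, "D01"] <- ifelse(pm$labels == 1, runif(nrow(X), 10, 20),
                       runif(nrow(X), 30, 40))
  catS <- buildRangeCatalog(X, pm$labels, n_bins = 4)
  d1 <- catS@ranges[[which(catS@descriptors == "D01")]]
  expect_equal(max(d1$mcc1d), 1.0)
  # degenerate constant descriptor flagged, single range
  X[, "D02"] <- 5
  catC <- buildRangeCatalog(X, pm$labels, n_bins = 4)
  i <- which(catC@descriptors == "D02")
  expect_true(catC@degenerate[i])
  expect_identical(nrow(catC@ranges[[i]]), 1L)
  # single-class labels rejected
  expect_error(buildRangeCatalog(pm$X, rep(1L, nrow(pm$X))), "both classes")
})

test_that("evaluateFilter counts and MCC match direct computation", {
  pm <- makePlantedMatrix(seed = 5)
  tab <- pm$X
  f <- new("IseFilter", ranges = data.frame(
    descriptor = colnames(tab)[1:5],
    low = rep(40, 5), high = rep(60, 5), stringsAsFactors = FALSE))
  ev <- evaluateFilter(f, tab, pm$labels)
  expect_identical(unname(ev@counts["tp"]), 20L)
  expect_identical(unname(ev@counts["fp"]), 0L)
  expect_equal(ev@mcc, 1.0)
  # stated example: tp=4 fp=1 tn=95 fn=0 -> MCC ~ 0.890
  expect_equal(oracleMcc(4, 1, 95, 0), 0.8897565, tolerance = 1e-6)
  # zero-pass filter gets the zero-denominator convention
  f0 <- new("IseFilter", ranges = data.frame(
    descriptor = colnames(tab)[1:5],
    low = rep(-10, 5), high = rep(-5, 5), stringsAsFactors = FALSE))
  ev0 <- evaluateFilter(f0, tab, pm$labels)
  expect_identical(ev0@mcc, 0)
  # missing descriptor errors with its name
  fBad <- new("IseFilter", ranges = data.frame(
    descriptor = c(colnames(tab)[1:4], "NOPE"),
    low = rep(0, 5), high = rep(1, 5), stringsAsFactors = FALSE))
  expect_error(evaluateFilter(fBad, tab, pm$labels), "NOPE")
})

test_that("evaluateFilter MCC agrees with an independent implementation", {
  set.seed(42)
  pm <- makePlantedMatrix(n_act = 15, n_dec = 45, seed = 9)
  for (i in 1:25) {
    lo <- runif(5, 0, 80)
    f <- new("IseFilter", ranges = data.frame(
      descriptor = sample(colnames(pm$X), 5),
      low = lo, high = lo + runif(5, 5, 40), stringsAsFactors = FALSE))
    ev <- evaluateFilter(f, pm$X, pm$labels)
    expect_equal(ev@mcc,
                 oracleMcc(ev@counts["tp"], ev@counts["fp"],
                           ev@counts["tn"], ev@counts["fn"]),
                 tolerance = 1e-12)
    expect_identical(sum(ev@counts), length(pm$labels))
  }
})

test_that("countCombinations equals closed form and brute-force count", {
  pm <- makePlantedMatrix(seed = 2)
  # 6 descriptors, 2 bins -> 3 ranges each: C(6,5) * 3^5
  cat2 <- buildRangeCatalog(pm$X, pm$labels, n_bins = 2)
  expect_equal(countCombinations(cat2), choose(6, 5) * 3^5)
  # brute-force agreement on catalogs up to 1e4 combinations,
  # including uneven per-descriptor range counts
  for (nb in 1:2) {
    cc <- buildRangeCatalog(pm$X, pm$labels, n_bins = nb)
    cc@ranges[[2]] <- cc@ranges[[2]][1, , drop = FALSE]
    cc@ranges[[5]] <- cc@ranges[[5]][seq_len(min(2, nrow(cc@ranges[[5]]))),
                                     , drop = FALSE]
    k <- vapply(cc@ranges, nrow, integer(1))
    brute <- sum(apply(combn(length(k), 5), 2, function(s) prod(k[s])))
    expect_lt(brute, 1e4 + 1)
    expect_equal(countCombinations(cc), brute)
  }
  # fewer than five descriptors -> 0
  cat4 <- buildRangeCatalog(pm$X[, 1:4], pm$labels, n_bins = 2)
  expect_identical(countCombinations(cat4), 0)
})

test_that("exhaustive search ranks the planted separating filter first", {
  pm <- makePlantedMatrix(seed = 7)
  catg <- buildRangeCatalog(pm$X, pm$labels, n_bins = 2)
  fs <- exhaustiveSearch(catg, pm$X, pm$labels)
  expect_identical(length(fs), as.integer(countCombinations(catg)))
  expect_false(is.unsorted(-fs@mcc))
  top <- getFilter(fs, 1)
  expect_equal(top@mcc, 1.0)
  expect_setequal(top@ranges$descriptor, sprintf("D%02d", 1:5))
  # threshold violation names the count
  expect_error(exhaustiveSearch(catg, pm$X, pm$labels, threshold = 10),
               "1458")
})

test_that("stochastic iteration eliminates planted-bad ranges, keeps ties", {
  pm <- makePlantedMatrix(n_act = 30, n_dec = 60, seed = 13)
  catg <- buildRangeCatalog(pm$X, pm$labels, n_bins = 4)
  # elim_fraction = 0 leaves the catalog unchanged
  set.seed(1)
  it0 <- stochasticIteration(catg, pm$X, pm$labels, sample_size_t = 2000,
                             elim_fraction = 0)
  expect_identical(it0$n_eliminated, 0L)
  expect_identical(it0$catalog@ranges, catg@ranges)
  # a decoy-only range is among those eliminated under the relaxed rule
  set.seed(2)
  it <- stochasticIteration(catg, pm$X, pm$labels, sample_size_t = 20000,
                            elim_fraction = 0.3, min_observations = 20,
                            decile_rule = FALSE)
  expect_gt(it$n_eliminated, 0L)
  r <- it$report
  elim <- r[r$eliminated, ]
  kept <- r[!r$eliminated, ]
  # eliminated ranges have worse mean MCC than the retained median
  expect_lt(max(elim$mean_mcc), stats::median(kept$mean_mcc))
  expect_error(stochasticIteration(catg, pm$X, pm$labels,
                                   sample_size_t = 0), "sample_size_t")
})

test_that("elimination never removes ranges of a perfect planted filter", {
  pm <- makePlantedMatrix(n_act = 25, n_dec = 75, n_desc = 8, seed = 17)
  catg <- buildRangeCatalog(pm$X, pm$labels, n_bins = 3)
  # the full-span range of each planted descriptor separates perfectly;
  # over 50 seeded iterations it must never be eliminated
  planted <- sprintf("D%02d", 1:5)
  fullSpan <- lapply(seq_along(catg@descriptors), function(d) {
    rt <- catg@ranges[[d]]
    c(min(rt$low), max(rt$high))
  })
  for (s in 1:50) {
    set.seed(s)
    it <- stochasticIteration(catg, pm$X, pm$labels, sample_size_t = 5000,
                              elim_fraction = 0.25, min_observations = 10)
    r <- it$report
    for (d in planted) {
      i <- which(catg@descriptors == d)
      sel <- r$descriptor == d & r$low == fullSpan[[i]][1] &
             r$high == fullSpan[[i]][2]
      expect_true(any(sel))
      expect_false(any(r$eliminated[sel]))
    }
  }
})

test_that("runIse is deterministic and respects the control-flow contract", {
  pm <- makePlantedMatrix(seed = 19)
  cfg <- iseConfig(n_bins = 2, seed = 99, max_filters = 50)
  m1 <- runIse(pm$X, pm$labels, cfg)
  m2 <- runIse(pm$X, pm$labels, cfg)
  # tiny catalog -> straight to exhaustive, zero stochastic iterations
  expect_identical(m1@config$iterations, 0L)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  writeModelJson(m1, p1); writeModelJson(m2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # retained MCCs non-increasing; planted filter recovered at rank 1
  expect_false(is.unsorted(-filterMcc(m1)))
  expect_equal(filterMcc(m1)[1], 1.0)
  expect_error(runIse(pm$X[, 1:4], pm$labels), "five descriptors")
})

test_that("model JSON round-trip is bit-exact", {
  pm <- makePlantedMatrix(seed = 23)
  m <- runIse(pm$X, pm$labels, iseConfig(n_bins = 2, seed = 5))
  p1 <- tempfile(fileext = ".json")
  writeModelJson(m, p1)
  m2 <- readModelJson(p1)
  expect_identical(m2@filters@lows, m@filters@lows)
  expect_identical(m2@filters@highs, m@filters@highs)
  expect_identical(m2@filters@mcc, m@filters@mcc)
  expect_identical(m2@filters@descriptors, m@filters@descriptors)
  expect_identical(m2@weightsScheme, m@weightsScheme)
  p2 <- tempfile(fileext = ".json")
  writeModelJson(m2, p2)
  expect_identical(readLines(p2), readLines(p1))
})
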