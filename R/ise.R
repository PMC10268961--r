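## ISE core: candidate range construction, stochastic elimination, exhaustive
## enumeration, model assembly.

.tableMatrix <- function(table) {
  if (is(table, "DescriptorTable")) table@values
  else if (is.matrix(table) && is.numeric(table)) table
  else stop("table must be a DescriptorTable or a numeric matrix")
}

.checkLabels <- function(labels, n) {
  labels <- as.integer(labels)
  if (length(labels) != n)
    stop("labels must be parallel to the table rows")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!any(labels == 1L) || !any(labels == 0L))
    stop("both classes (actives and decoys) must be present")
  labels
}

#' Build the candidate range catalog for every descriptor
#'
#' Candidate ranges are all contiguous unions of quantile bins of the
#' active-class distribution of each descriptor: `n_bins` bins give
#' `n_bins * (n_bins + 1) / 2` closed candidate intervals. Each candidate is
#' scored as a one-descriptor classifier and carried with its
#' single-descriptor MCC. Constant descriptors yield a single degenerate
#' range and are flagged. Descriptors are ordered lexicographically (C
#' locale) and ranges by (low, high), fixing the deterministic enumeration
#' and tie-break order used downstream.
#'
#' Bin-edge placement is outlier-robust: active values outside
#' median +/- `mad_fence` * MAD are ignored when the quantile edges are
#' placed (they are still scored), so a few mislabelled decoys cannot
#' stretch the candidate ranges across the whole decoy support. With clean
#' labels and a unimodal active class the fence keeps every active and the
#' edges are the plain active quantiles.
#'
#' @param table a [DescriptorTable-class] or numeric matrix with dimnames.
#' @param labels 0/1 vector (1 = active), parallel to rows.
#' @param n_bins number of active-quantile bins.
#' @param mad_fence half-width of the robust edge-placement fence in MADs;
#'   NULL disables the fence.
#' @return a [RangeCatalog-class].
#' @export
buildRangeCatalog <- function(table, labels, n_bins = 8L, mad_fence = 3.5) {
  X <- .tableMatrix(table)
  labels <- .checkLabels(labels, nrow(X))
  stopifnot(n_bins >= 1)
  ord <- order(colnames(X), method = "radix")
  X <- X[, ord, drop = FALSE]
  act <- labels == 1L
  nAct <- sum(act); nDec <- sum(!act)
  ranges <- vector("list", ncol(X))
  degen <- logical(ncol(X))
  for (j in seq_len(ncol(X))) {
    v <- X[, j]
    av <- v[act]
    if (!is.null(mad_fence)) {
      med <- stats::median(av)
      m <- stats::mad(av)
      if (m > 0) {
        inFence <- abs(av - med) <= mad_fence * m
        if (sum(inFence) >= 2) av <- av[inFence]
      }
    }
    edges <- unique(quantile(av, probs = seq(0, 1, length.out = n_bins + 1),
                             names = FALSE, type = 7))
    if (length(edges) == 1L) {
      rt <- data.frame(low = edges, high = edges)
      degen[j] <- TRUE
    } else {
      B <- length(edges)
      idx <- which(upper.tri(matrix(0, B, B)), arr.ind = TRUE)
      rt <- data.frame(low = edges[idx[, 1]], high = edges[idx[, 2]])
      rt <- unique(rt)
    }
    # single-descriptor confusion for each candidate
    mcc1 <- numeric(nrow(rt))
    for (r in seq_len(nrow(rt))) {
      pass <- v >= rt$low[r] & v <= rt$high[r]
      tp <- sum(pass & act); fp <- sum(pass) - tp
      mcc1[r] <- .mccCounts(tp, fp, nDec - fp, nAct - tp)
    }
    rt$mcc1d <- mcc1
    o <- order(rt$low, rt$high, method = "radix")
    ranges[[j]] <- rt[o, , drop = FALSE]
    rownames(ranges[[j]]) <- NULL
  }
  new("RangeCatalog", descriptors = colnames(X), ranges = ranges,
      degenerate = degen)
}

.mccCounts <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  prod <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (prod <= 0) return(0)
  (tp * tn - fp * fn) / sqrt(prod)
}

#' Count the five-descriptor filter combinations in a catalog
#'
#' The number of distinct filters is the degree-5 elementary symmetric
#' polynomial of the per-descriptor surviving-range counts, computed by
#' dynamic programming and never by enumeration.
#'
#' @param catalog a [RangeCatalog-class].
#' @return a (double) count; 0 when fewer than five descriptors survive.
#' @export
countCombinations <- function(catalog) {
  stopifnot(is(catalog, "RangeCatalog"))
  k <- vapply(catalog@ranges, nrow, integer(1))
  if (length(k) < 5L) return(0)
  e <- c(1, numeric(5))
  for (ki in k) for (j in 6:2) e[j] <- e[j] + e[j - 1] * ki
  e[6]
}

#' Evaluate a five-range filter against a labelled descriptor table
#'
#' A molecule passes iff all five of its values lie inside the closed
#' ranges; tp/fp/tn/fn are tallied and the Matthews correlation computed,
#' with the zero-denominator convention MCC = 0.
#'
#' @param filter an [IseFilter-class] (counts may be unset).
#' @param table a [DescriptorTable-class] or numeric matrix.
#' @param labels 0/1 vector.
#' @return the filter with counts and mcc filled in.
#' @export
evaluateFilter <- function(filter, table, labels) {
  stopifnot(is(filter, "IseFilter"))
  X <- .tableMatrix(table)
  labels <- .checkLabels(labels, nrow(X))
  idx <- match(filter@ranges$descriptor, colnames(X))
  if (anyNA(idx))
    stop("descriptor(s) missing from table: ",
         paste(filter@ranges$descriptor[is.na(idx)], collapse = ", "))
  res <- cpp_eval_filters(X, labels, matrix(idx, 1),
                          matrix(filter@ranges$low, 1),
                          matrix(filter@ranges$high, 1))
  filter@counts <- c(tp = res$tp[1], fp = res$fp[1],
                     tn = res$tn[1], fn = res$fn[1])
  filter@mcc <- res$mcc[1]
  validObject(filter)
  filter
}

.catalogRangeList <- function(catalog) {
  lapply(catalog@ranges, function(rt) cbind(rt$low, rt$high))
}

.catalogColumns <- function(catalog, X) {
  idx <- match(catalog@descriptors, colnames(X))
  if (anyNA(idx))
    stop("catalog descriptor(s) missing from table: ",
         paste(catalog@descriptors[is.na(idx)], collapse = ", "))
  X[, idx, drop = FALSE]
}

#' Exhaustively enumerate and rank all remaining filter combinations
#'
#' Every combination of five distinct descriptors with one surviving range
#' each is evaluated; the full list is returned sorted by MCC descending
#' with the deterministic lexicographic tie-break on (descriptor names,
#' low, high).
#'
#' @param catalog a [RangeCatalog-class].
#' @param table descriptor table or matrix.
#' @param labels 0/1 vector.
#' @param threshold refuse to enumerate catalogs at or above this many
#'   combinations (names the count in the error).
#' @return a [FilterSet-class], sorted.
#' @export
exhaustiveSearch <- function(catalog, table, labels, threshold = 1e6) {
  stopifnot(is(catalog, "RangeCatalog"))
  X <- .tableMatrix(table)
  labels <- .checkLabels(labels, nrow(X))
  cc <- countCombinations(catalog)
  if (cc >= threshold)
    stop(sprintf(
      "catalog holds %.0f combinations, not below the exhaustive threshold %.0f",
      cc, threshold))
  if (cc == 0) stop("fewer than five descriptors in the catalog")
  Xc <- .catalogColumns(catalog, X)
  res <- cpp_exhaustive(Xc, labels, .catalogRangeList(catalog), threshold)
  # flat per-(descriptor, range) lookup for the bounds
  k <- vapply(catalog@ranges, nrow, integer(1))
  offs <- c(0L, cumsum(k))
  lowFlat <- unlist(lapply(catalog@ranges, `[[`, "low"), use.names = FALSE)
  highFlat <- unlist(lapply(catalog@ranges, `[[`, "high"), use.names = FALSE)
  flat <- offs[res$didx] + res$ridx
  dim(flat) <- dim(res$didx)
  fs <- new("FilterSet",
            descriptors = matrix(catalog@descriptors[res$didx],
                                 ncol = 5),
            lows = matrix(lowFlat[flat], ncol = 5),
            highs = matrix(highFlat[flat], ncol = 5),
            tp = res$tp, fp = res$fp, tn = res$tn, fn = res$fn,
            mcc = res$mcc)
  # stable sort: ties keep enumeration order, which is the lexicographic
  # (descriptor name, low, high) order by construction
  fs[order(-fs@mcc, method = "radix")]
}

#' One stochastic elimination iteration
#'
#' Samples `sample_size_t` filters uniformly (five distinct descriptors, one
#' surviving range each), accumulates per-range statistics (observation
#' count, mean filter MCC, share of appearances in the top and bottom score
#' deciles), and eliminates ranges that (a) were observed at least
#' `min_observations` times, (b) have mean MCC strictly below the
#' `elim_fraction` quantile of eligible means (a tie at the cut never
#' splits), and (c) with `decile_rule = TRUE`, are over-represented in the
#' bottom decile (share > 0.1) while under-represented in the top decile
#' (share < 0.1). A descriptor is never taken below
#' `min_ranges_per_descriptor` surviving ranges. Uses the current R RNG
#' state; seed via [set.seed()] or [runIse()].
#'
#' @param catalog a [RangeCatalog-class].
#' @param table descriptor table or matrix.
#' @param labels 0/1 vector.
#' @param sample_size_t filters to sample.
#' @param elim_fraction fraction of eligible ranges marked by mean MCC.
#' @param min_observations minimum observations before elimination.
#' @param min_ranges_per_descriptor survivor floor per descriptor.
#' @param decile_rule apply the decile over/under-representation condition.
#' @return list with elements `catalog` (pruned), `report` (per-range
#'   statistics with an `eliminated` flag) and `n_eliminated`.
#' @export
stochasticIteration <- function(catalog, table, labels, sample_size_t = 1e5,
                                elim_fraction = 0.2, min_observations = 30L,
                                min_ranges_per_descriptor = 1L,
                                decile_rule = TRUE) {
  stopifnot(is(catalog, "RangeCatalog"))
  if (sample_size_t < 1) stop("sample_size_t must be >= 1")
  X <- .tableMatrix(table)
  labels <- .checkLabels(labels, nrow(X))
  Xc <- .catalogColumns(catalog, X)
  sm <- cpp_sample_filters(Xc, labels, .catalogRangeList(catalog),
                           as.integer(sample_size_t))
  k <- vapply(catalog@ranges, nrow, integer(1))
  offs <- c(0L, cumsum(k))
  total <- sum(k)
  idvec <- as.vector(offs[sm$didx] + sm$ridx)
  mccvec <- rep(sm$mcc, times = 5)
  obs <- tabulate(idvec, nbins = total)
  summcc <- numeric(total)
  rs <- rowsum(mccvec, idvec)
  summcc[as.integer(rownames(rs))] <- rs[, 1]
  qlo <- quantile(sm$mcc, 0.1, names = FALSE)
  qhi <- quantile(sm$mcc, 0.9, names = FALSE)
  botCount <- tabulate(idvec[rep(sm$mcc <= qlo, 5)], nbins = total)
  topCount <- tabulate(idvec[rep(sm$mcc >= qhi, 5)], nbins = total)
  meanmcc <- ifelse(obs > 0, summcc / obs, NA_real_)
  botShare <- ifelse(obs > 0, botCount / obs, NA_real_)
  topShare <- ifelse(obs > 0, topCount / obs, NA_real_)

  descOf <- rep(seq_along(k), times = k)
  # only ranges of descriptors still above the survivor floor are
  # eliminable; the elim_fraction cut is taken over those, so the search
  # keeps progressing once weak descriptors are pinned at the floor
  eligible <- obs >= min_observations &
    k[descOf] > min_ranges_per_descriptor
  cand <- rep(FALSE, total)
  if (elim_fraction > 0 && any(eligible)) {
    cut <- quantile(meanmcc[eligible], elim_fraction, names = FALSE)
    cand <- eligible & !is.na(meanmcc) & meanmcc < cut
    if (decile_rule)
      cand <- cand & botShare > 0.1 & topShare < 0.1
  }
  # survivor floor: spare the best-mean candidates of an over-pruned descriptor
  for (d in seq_along(k)) {
    ci <- which(cand & descOf == d)
    keepAfter <- k[d] - length(ci)
    if (length(ci) && keepAfter < min_ranges_per_descriptor) {
      spare <- min_ranges_per_descriptor - keepAfter
      ci <- ci[order(-meanmcc[ci])]
      cand[ci[seq_len(min(spare, length(ci)))]] <- FALSE
    }
  }
  report <- data.frame(
    descriptor = catalog@descriptors[descOf],
    low = unlist(lapply(catalog@ranges, `[[`, "low"), use.names = FALSE),
    high = unlist(lapply(catalog@ranges, `[[`, "high"), use.names = FALSE),
    observations = obs, mean_mcc = meanmcc,
    bottom_share = botShare, top_share = topShare,
    eliminated = cand)
  newRanges <- catalog@ranges
  for (d in seq_along(k)) {
    drop <- which(cand[descOf == d])
    if (length(drop)) {
      newRanges[[d]] <- newRanges[[d]][-drop, , drop = FALSE]
      rownames(newRanges[[d]]) <- NULL
    }
  }
  out <- new("RangeCatalog", descriptors = catalog@descriptors,
             ranges = newRanges, degenerate = catalog@degenerate)
  list(catalog = out, report = report, n_eliminated = sum(cand))
}

#' Build an ISE model: iterate, enumerate exhaustively, retain top filters
#'
#' Runs the full ISE loop: build the range catalog, run stochastic
#' elimination iterations until the number of five-range combinations drops
#' below the exhaustive threshold, enumerate and rank all survivors, and
#' retain the top `min(max_filters, ceiling(retain_fraction * enumerated))`
#' filters. The returned model carries the full configuration (seed
#' included); identical inputs and seed give an identical model.
#'
#' If an iteration eliminates nothing while the catalog is still above the
#' threshold, the iteration is retried with the decile condition relaxed
#' (mean-MCC criterion alone) so the search provably progresses.
#'
#' @param table a [DescriptorTable-class] or numeric matrix.
#' @param labels 0/1 vector (1 = active).
#' @param config an [iseConfig()] list.
#' @return an [IseModel-class].
#' @export
runIse <- function(table, labels, config = iseConfig()) {
  config <- asIseConfig(config)
  X <- .tableMatrix(table)
  labels <- .checkLabels(labels, nrow(X))
  if (ncol(X) < 5) stop("at least five descriptors are required")
  set.seed(config$seed)
  catalog <- buildRangeCatalog(X, labels, config$n_bins)
  iterations <- 0L
  cc0 <- countCombinations(catalog)
  while ((cc <- countCombinations(catalog)) >= config$exhaustive_threshold) {
    if (iterations >= config$max_iterations)
      stop(sprintf(
        "stochastic elimination did not reach %.0f combinations in %d iterations (at %.0f)",
        config$exhaustive_threshold, config$max_iterations, cc))
    it <- stochasticIteration(catalog, X, labels,
                              sample_size_t = config$sample_size_t,
                              elim_fraction = config$elim_fraction,
                              min_observations = config$min_observations,
                              min_ranges_per_descriptor =
                                config$min_ranges_per_descriptor,
                              decile_rule = TRUE)
    if (it$n_eliminated == 0L)
      it <- stochasticIteration(catalog, X, labels,
                                sample_size_t = config$sample_size_t,
                                elim_fraction = config$elim_fraction,
                                min_observations = config$min_observations,
                                min_ranges_per_descriptor =
                                  config$min_ranges_per_descriptor,
                                decile_rule = FALSE)
    if (it$n_eliminated == 0L)
      stop("stochastic elimination stalled: no range satisfies the ",
           "elimination rule")
    catalog <- it$catalog
    iterations <- iterations + 1L
  }
  if (length(catalog@descriptors) < 5)
    stop("catalog collapsed below five descriptors")
  fs <- exhaustiveSearch(catalog, X, labels,
                         threshold = config$exhaustive_threshold)
  nEnum <- length(fs)
  cap <- min(config$max_filters, ceiling(config$retain_fraction * nEnum))
  cap <- max(1, min(cap, nEnum))
  retained <- fs[seq_len(cap)]
  new("IseModel", filters = retained,
      weightsScheme = config$weights_scheme,
      config = c(unclass(config),
                 list(iterations = iterations, enumerated = nEnum,
                      combinations_initial = cc0)),
      descriptors = sort(unique(as.vector(retained@descriptors)),
                         method = "radix"))
}
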