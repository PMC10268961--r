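#' @import methods
#' @importFrom stats quantile sd cor rnorm runif setNames
#' @importFrom utils head read.csv write.csv combn
#' @useDynLib isescreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DESCRIPTOR_FAMILIES <- c(
  "partial_charge", "atom_bond_counts", "pharmacophore_feature",
  "physical_properties", "subdivided_surface_areas",
  "adjacency_distance_matrix", "kier_hall_connectivity"
)

#' DescriptorTable: molecules x named numeric 2D descriptors
#'
#' Dense numeric matrix of per-molecule 2D descriptor values, with a total
#' mapping from each descriptor name to one of the seven descriptor families
#' (partial charge, atom/bond counts, pharmacophore features, physical
#' properties, subdivided surface areas, adjacency/distance-matrix indices,
#' Kier-Hall connectivity).
#'
#' @slot values numeric matrix, rows = molecules (rownames = molecule ids),
#'   columns = descriptors (colnames = descriptor names); no missing values.
#' @slot family named character vector mapping every descriptor name to its
#'   family.
#' @export
setClass("DescriptorTable",
  representation(values = "matrix", family = "character"),
  validity = function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      msg <- c(msg, "molecule ids (rownames) must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      msg <- c(msg, "descriptor names (colnames) must be present and unique")
    if (anyNA(v)) msg <- c(msg, "values must not contain missing entries")
    miss <- setdiff(colnames(v), names(object@family))
    if (length(miss))
      msg <- c(msg, paste0("family map missing descriptors: ",
                           paste(head(miss, 5), collapse = ", ")))
    bad <- setdiff(unique(object@family), DESCRIPTOR_FAMILIES)
    if (length(bad))
      msg <- c(msg, paste0("unknown families: ", paste(bad, collapse = ", ")))
    if (length(msg)) msg else TRUE
  }
)

#' A single five-range ISE filter
#'
#' A conjunction of exactly five closed descriptor-value ranges on five
#' distinct descriptors. A molecule "passes" the filter iff all five of its
#' descriptor values lie inside the corresponding ranges. Confusion counts
#' and the Matthews correlation coefficient are attached once the filter has
#' been evaluated against a labelled set.
#'
#' @slot ranges data.frame with columns descriptor (character), low, high
#'   (numeric, low <= high), exactly five rows, distinct descriptors.
#' @slot counts integer vector (tp, fp, tn, fn); NA before evaluation.
#' @slot mcc numeric in [-1, 1]; NA before evaluation.
#' @export
setClass("IseFilter",
  representation(ranges = "data.frame", counts = "integer", mcc = "numeric"),
  prototype(counts = c(tp = NA_integer_, fp = NA_integer_,
                       tn = NA_integer_, fn = NA_integer_),
            mcc = NA_real_),
  validity = function(object) {
    r <- object@ranges
    msg <- character()
    if (!all(c("descriptor", "low", "high") %in% names(r)))
      msg <- c(msg, "ranges needs columns descriptor, low, high")
    else {
      if (nrow(r) != 5L) msg <- c(msg, "a filter holds exactly five ranges")
      if (anyDuplicated(r$descriptor))
        msg <- c(msg, "the five ranges must be on distinct descriptors")
      if (any(r$low > r$high)) msg <- c(msg, "ranges must satisfy low <= high")
    }
    if (!all(c("tp", "fp", "tn", "fn") %in% names(object@counts)))
      msg <- c(msg, "counts must be named tp, fp, tn, fn")
    if (!is.na(object@mcc) && (object@mcc < -1 || object@mcc > 1))
      msg <- c(msg, "mcc must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' A columnar collection of evaluated filters
#'
#' Column-oriented storage for many filters (descriptor-name matrix plus low
#' and high bound matrices, one row per filter, five columns), with their
#' confusion counts and MCC values. Used for exhaustive-search results and as
#' the filter store inside an [IseModel-class].
#'
#' @slot descriptors character matrix (n x 5) of descriptor names.
#' @slot lows,highs numeric matrices (n x 5) of closed range bounds.
#' @slot tp,fp,tn,fn integer vectors of confusion counts.
#' @slot mcc numeric vector, Matthews correlation per filter.
#' @export
setClass("FilterSet",
  representation(descriptors = "matrix", lows = "matrix", highs = "matrix",
                 tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer", mcc = "numeric"),
  validity = function(object) {
    n <- nrow(object@descriptors)
    msg <- character()
    dims <- vapply(list(object@descriptors, object@lows, object@highs),
                   function(m) all(dim(m) == c(n, 5L)), logical(1))
    if (!all(dims)) msg <- c(msg, "descriptors/lows/highs must all be n x 5")
    lens <- vapply(list(object@tp, object@fp, object@tn, object@fn,
                        object@mcc), length, integer(1))
    if (!all(lens == n)) msg <- c(msg, "count/mcc vectors must have length n")
    if (n > 0 && any(object@lows > object@highs))
      msg <- c(msg, "ranges must satisfy low <= high")
    if (length(msg)) msg else TRUE
  }
)

#' An ISE classification model
#'
#' An MCC-ranked ensemble of five-range filters together with the full build
#' configuration (including the seed), the weighting scheme used by the
#' [-1, +1] screening index, and the descriptor names the model constrains.
#'
#' @slot filters a [FilterSet-class], sorted by MCC descending with a
#'   deterministic lexicographic tie-break.
#' @slot weightsScheme one of "unit", "mcc", "fscore".
#' @slot config named list of build parameters (seed included).
#' @slot descriptors character vector of descriptor names used.
#' @export
setClass("IseModel",
  representation(filters = "FilterSet", weightsScheme = "character",
                 config = "list", descriptors = "character"),
  validity = function(object) {
    msg <- character()
    if (!object@weightsScheme %in% c("unit", "mcc", "fscore"))
      msg <- c(msg, "weightsScheme must be unit, mcc or fscore")
    m <- object@filters@mcc
    if (length(m) > 1 && any(diff(m) > 1e-12))
      msg <- c(msg, "filters must be sorted by MCC, non-increasing")
    if (length(msg)) msg else TRUE
  }
)

#' Range catalog: surviving candidate ranges per descriptor
#'
#' For each descriptor, the list of candidate closed ranges still alive in
#' the ISE search, each carrying its single-descriptor MCC. Descriptors are
#' kept in C-locale lexicographic name order and ranges in (low, high) order
#' so that exhaustive enumeration order is deterministic.
#'
#' @slot descriptors character vector (sorted).
#' @slot ranges list (parallel to descriptors) of data.frames with columns
#'   low, high, mcc1d.
#' @slot degenerate logical vector flagging constant descriptors.
#' @export
setClass("RangeCatalog",
  representation(descriptors = "character", ranges = "list",
                 degenerate = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@ranges) != length(object@descriptors))
      msg <- c(msg, "one range table per descriptor required")
    n <- vapply(object@ranges, nrow, integer(1))
    if (length(n) && any(n < 1L))
      msg <- c(msg, "every descriptor must keep at least one range")
    for (rt in object@ranges) {
      if (anyDuplicated(rt[, c("low", "high")])) {
        msg <- c(msg, "ranges of one descriptor must be distinct"); break
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' A curated learning set of actives and property-matched decoys
#'
#' @slot actives data.frame with columns id, smiles.
#' @slot decoys data.frame with columns id, smiles.
#' @slot ratio integer, requested decoy:active dilution.
#' @slot provenance list; curation audit and decoy-sampling metadata,
#'   including a `shortfall` flag when the eligible pool could not supply
#'   ratio x n_actives decoys.
#' @export
setClass("LearningSet",
  representation(actives = "data.frame", decoys = "data.frame",
                 ratio = "integer", provenance = "list"),
  validity = function(object) {
    msg <- character()
    if (anyDuplicated(c(object@actives$id, object@decoys$id)))
      msg <- c(msg, "active and decoy ids must be disjoint and unique")
    full <- nrow(object@decoys) == object@ratio * nrow(object@actives)
    if (!full && !isTRUE(object@provenance$shortfall))
      msg <- c(msg,
        "decoys must number ratio x actives unless flagged as a shortfall")
    if (length(msg)) msg else TRUE
  }
)

#' Applicability domain over MW, clogP, HBA, HBD
#'
#' Per-property mean and sample standard deviation of the actives; decoys are
#' drawn only from pool members inside mean +/- 2 SD on all four properties.
#'
#' @slot stats numeric matrix, rows = c("mean","sd"),
#'   cols = c("MW","clogP","HBA","HBD").
#' @export
setClass("ApplicabilityDomain",
  representation(stats = "matrix"),
  validity = function(object) {
    s <- object@stats
    if (!identical(rownames(s), c("mean", "sd")) ||
        !identical(colnames(s), AD_PROPERTIES))
      return("stats must be a 2 x 4 matrix: mean/sd x MW,clogP,HBA,HBD")
    if (any(s["sd", ] < 0)) return("standard deviations must be >= 0")
    TRUE
  }
)

AD_PROPERTIES <- c("MW", "clogP", "HBA", "HBD")

#' Cross-validation fold assignment
#'
#' @slot scheme "kfold" (stratified) or "loo" (leave-one-active-out).
#' @slot folds named integer vector: molecule id -> fold index.
#' @export
setClass("FoldAssignment",
  representation(scheme = "character", folds = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@scheme %in% c("kfold", "loo"))
      msg <- c(msg, "scheme must be kfold or loo")
    if (is.null(names(object@folds)) || anyDuplicated(names(object@folds)))
      msg <- c(msg, "folds must be named by unique molecule ids")
    if (length(msg)) msg else TRUE
  }
)

#' Binary drug x target interaction matrix
#'
#' @slot mat binary (0/1) matrix, rows = drugs, cols = targets, dimnames set.
#' @slot kind "reported" or "predicted".
#' @export
setClass("InteractionMatrix",
  representation(mat = "matrix", kind = "character"),
  validity = function(object) {
    msg <- character()
    if (!all(object@mat %in% c(0, 1)))
      msg <- c(msg, "entries must be 0 or 1")
    if (is.null(rownames(object@mat)) || is.null(colnames(object@mat)))
      msg <- c(msg, "drug and target ids (dimnames) are required")
    if (!object@kind %in% c("reported", "predicted"))
      msg <- c(msg, "kind must be reported or predicted")
    if (length(msg)) msg else TRUE
  }
)

#' Synthetic descriptor fixture with planted ground-truth filters
#'
#' @slot table a [DescriptorTable-class].
#' @slot labels integer vector (1 = active, 0 = decoy), parallel to rows.
#' @slot planted list of [IseFilter-class] ground-truth boxes.
#' @slot noiseRate numeric label-noise rate.
#' @slot seed integer seed used for generation.
#' @export
setClass("PlantedFixture",
  representation(table = "DescriptorTable", labels = "integer",
                 planted = "list", noiseRate = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@labels) != nrow(object@table@values))
      msg <- c(msg, "labels must be parallel to the descriptor table rows")
    if (!all(object@labels %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0/1")
    if (length(msg)) msg else TRUE
  }
)

# ---- show methods -----------------------------------------------------------

setMethod("show", "DescriptorTable", function(object) {
  v <- object@values
  cat("DescriptorTable:", nrow(v), "molecules x", ncol(v), "descriptors\n")
  fam <- table(object@family[colnames(v)])
  cat("  families:", paste(names(fam), fam, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "IseFilter", function(object) {
  cat("IseFilter (5 ranges)\n")
  r <- object@ranges
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %s in [%.4g, %.4g]\n", r$descriptor[i], r$low[i], r$high[i]))
  if (!is.na(object@mcc))
    cat(sprintf("  MCC %.4f (tp=%d fp=%d tn=%d fn=%d)\n", object@mcc,
        object@counts["tp"], object@counts["fp"],
        object@counts["tn"], object@counts["fn"]))
})

setMethod("show", "FilterSet", function(object) {
  n <- length(object@mcc)
  cat("FilterSet of", n, "filters")
  if (n) cat(sprintf("; MCC range [%.4f, %.4f]", min(object@mcc),
                     max(object@mcc)))
  cat("\n")
})

setMethod("show", "IseModel", function(object) {
  cat("IseModel:", length(object@filters@mcc), "filters on",
      length(object@descriptors), "descriptors; weights:",
      object@weightsScheme, "\n")
  if (length(object@filters@mcc))
    cat(sprintf("  top filter MCC %.4f\n", object@filters@mcc[1]))
})

setMethod("show", "RangeCatalog", function(object) {
  nr <- vapply(object@ranges, nrow, integer(1))
  cat("RangeCatalog:", length(object@descriptors), "descriptors,",
      sum(nr), "ranges;", format(countCombinations(object), big.mark = ","),
      "five-descriptor combinations\n")
})

setMethod("show", "LearningSet", function(object) {
  cat("LearningSet:", nrow(object@actives), "actives +",
      nrow(object@decoys), "decoys (ratio", object@ratio, ")\n")
})

setMethod("show", "ApplicabilityDomain", function(object) {
  cat("ApplicabilityDomain (mean +/- 2 SD):\n")
  s <- object@stats
  for (p in colnames(s))
    cat(sprintf("  %-5s [%.3g, %.3g]\n", p,
        s["mean", p] - 2 * s["sd", p], s["mean", p] + 2 * s["sd", p]))
})

setMethod("show", "FoldAssignment", function(object) {
  cat("FoldAssignment:", object@scheme, "with",
      length(unique(object@folds)), "folds over",
      length(object@folds), "molecules\n")
})

setMethod("show", "InteractionMatrix", function(object) {
  cat("InteractionMatrix (", object@kind, "): ", nrow(object@mat),
      " drugs x ", ncol(object@mat), " targets, ",
      sum(object@mat), " interactions\n", sep = "")
})

setMethod("show", "PlantedFixture", function(object) {
  cat("PlantedFixture:", sum(object@labels == 1L), "actives +",
      sum(object@labels == 0L), "decoys,",
      length(object@planted), "planted filters, noise",
      object@noiseRate, "\n")
})

# ---- accessors --------------------------------------------------------------

#' @describeIn DescriptorTable-class molecule ids
#' @param x object
#' @export
molIds <- function(x) {
  if (is(x, "DescriptorTable")) rownames(x@values)
  else if (is(x, "PlantedFixture")) rownames(x@table@values)
  else stop("no molecule ids for class ", class(x))
}

#' @describeIn DescriptorTable-class descriptor names
#' @export
descriptorNames <- function(x) {
  if (is(x, "DescriptorTable")) colnames(x@values)
  else if (is(x, "IseModel")) x@descriptors
  else stop("no descriptor names for class ", class(x))
}

#' @describeIn DescriptorTable-class the numeric value matrix
#' @export
descValues <- function(x) x@values

#' @describeIn DescriptorTable-class named descriptor -> family map
#' @export
descriptorFamilies <- function(x) x@family[colnames(x@values)]

#' Number of filters in a FilterSet or IseModel
#' @param x a FilterSet or IseModel
#' @export
nFilters <- function(x) {
  if (is(x, "IseModel")) x <- x@filters
  length(x@mcc)
}

#' Extract one filter as an IseFilter object
#' @param x a FilterSet or IseModel
#' @param i filter index (1-based, in stored order)
#' @export
getFilter <- function(x, i) {
  if (is(x, "IseModel")) x <- x@filters
  stopifnot(i >= 1, i <= length(x@mcc))
  new("IseFilter",
      ranges = data.frame(descriptor = x@descriptors[i, ],
                          low = x@lows[i, ], high = x@highs[i, ],
                          stringsAsFactors = FALSE),
      counts = c(tp = x@tp[i], fp = x@fp[i], tn = x@tn[i], fn = x@fn[i]),
      mcc = x@mcc[i])
}

#' Filter MCC values (stored order)
#' @param x a FilterSet or IseModel
#' @export
filterMcc <- function(x) {
  if (is(x, "IseModel")) x <- x@filters
  x@mcc
}

#' Subset a FilterSet by filter index
#' @param x FilterSet
#' @param i integer indices
#' @export
setMethod("[", "FilterSet", function(x, i, j, ..., drop = FALSE) {
  new("FilterSet",
      descriptors = x@descriptors[i, , drop = FALSE],
      lows = x@lows[i, , drop = FALSE], highs = x@highs[i, , drop = FALSE],
      tp = x@tp[i], fp = x@fp[i], tn = x@tn[i], fn = x@fn[i], mcc = x@mcc[i])
})

#' Length of a FilterSet (number of filters)
#' @param x FilterSet
#' @export
setMethod("length", "FilterSet", function(x) length(x@mcc))

#' A binary feature-set fingerprint
#'
#' Atom-pair features present in a molecule, stored as the set of integer
#' feature codes (stored as doubles: codes exceed 32-bit range).
#'
#' @slot bits sorted vector of distinct non-negative feature codes.
#' @export
setClass("Fingerprint",
  representation(bits = "numeric"),
  validity = function(object) {
    b <- object@bits
    if (any(b < 0)) return("feature codes must be non-negative")
    if (anyDuplicated(b)) return("feature codes must be distinct")
    TRUE
  }
)

setMethod("show", "Fingerprint", function(object) {
  cat("Fingerprint with", length(object@bits), "features\n")
})
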