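## Screening: the [-1, +1] index, library ranking, enrichment, cutoffs.

.modelMatrices <- function(model, X) {
  fs <- model@filters
  idx <- match(fs@descriptors, colnames(X))
  if (anyNA(idx)) {
    miss <- unique(fs@descriptors[is.na(idx)])
    stop("descriptor(s) missing from input: ", paste(miss, collapse = ", "))
  }
  list(didx = matrix(idx, ncol = 5), lo = fs@lows, hi = fs@highs)
}

#' Filter weights under a weighting scheme
#'
#' Unit weights give the +1/-1 reading of the screening index; "mcc" weights
#' each filter by max(MCC, eps); "fscore" by the harmonic mean of precision
#' and recall computed from the filter's training confusion counts.
#'
#' @param model an [IseModel-class].
#' @param scheme overrides the model's stored scheme if given.
#' @param eps floor applied to mcc/fscore weights so the total stays positive.
#' @return numeric weight vector, one per filter.
#' @export
filterWeights <- function(model, scheme = NULL, eps = 1e-6) {
  fs <- model@filters
  scheme <- if (is.null(scheme)) model@weightsScheme else scheme
  switch(scheme,
    unit = rep(1, length(fs)),
    mcc = pmax(fs@mcc, eps),
    fscore = {
      f <- 2 * fs@tp / (2 * fs@tp + fs@fp + fs@fn)
      f[!is.finite(f)] <- 0
      pmax(f, eps)
    },
    stop("unknown weights scheme: ", scheme))
}

#' Score a single molecule on the [-1, +1] index
#'
#' Each filter contributes +w if the molecule lies inside all five of its
#' closed ranges and -w otherwise; the index is the weight-normalized sum,
#' so passing every filter gives +1 and failing every filter gives -1. With
#' unit weights the index equals (passes - fails) / n exactly.
#'
#' @param model an [IseModel-class].
#' @param row named numeric vector supplying every model descriptor.
#' @return data.frame with molecule_id, index, n_filters_passed.
#' @export
scoreMolecule <- function(model, row) {
  X <- matrix(as.numeric(row), nrow = 1,
              dimnames = list("molecule", names(row)))
  res <- screenLibrary(model, X)
  res$rank <- NULL
  res
}

#' Screen a library and rank by the screening index
#'
#' @param model an [IseModel-class].
#' @param table a [DescriptorTable-class] or numeric matrix whose columns
#'   cover the model's descriptors.
#' @return data.frame (molecule_id, index, n_filters_passed, rank), sorted
#'   index-descending with ties broken on molecule_id.
#' @export
screenLibrary <- function(model, table) {
  stopifnot(is(model, "IseModel"))
  X <- .tableMatrix(table)
  if (nrow(X) == 0)
    return(data.frame(molecule_id = character(), index = numeric(),
                      n_filters_passed = integer(), rank = integer()))
  mm <- .modelMatrices(model, X)
  w <- filterWeights(model)
  sc <- cpp_score_library(X, mm$didx, mm$lo, mm$hi, w)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("M%06d", seq_len(nrow(X)))
  out <- data.frame(molecule_id = ids, index = sc$index,
                    n_filters_passed = sc$n_filters_passed)
  out <- out[order(-out$index, out$molecule_id, method = "radix"), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Enrichment factor of a ranked selection
#'
#' EF = (TP_in_selection / n_selected) / (N_positives / N_total): how much
#' richer the top of the ranked list is in actives than the library overall.
#'
#' @param ranked_labels 0/1 labels in rank order (best first).
#' @param n_selected size of the top selection.
#' @return the enrichment factor.
#' @export
enrichmentFactor <- function(ranked_labels, n_selected) {
  ranked_labels <- as.integer(ranked_labels)
  N <- length(ranked_labels)
  stopifnot(n_selected >= 1, n_selected <= N)
  P <- sum(ranked_labels == 1L)
  if (P == 0)
    stop(structure(class = c("iseNoPositives", "error", "condition"),
                   list(message = "enrichment factor undefined: no positives",
                        call = sys.call())))
  tpSel <- sum(ranked_labels[seq_len(n_selected)] == 1L)
  (tpSel / n_selected) / (P / N)
}

#' Per-cutoff confusion summary and recommended screening cutoff
#'
#' For each index cutoff, molecules with index strictly above the cutoff are
#' selected; TP, FP, TP/FP (Inf flagged when FP = 0 and TP > 0) and EF are
#' reported. The recommended cutoff is the highest one whose TP/FP is
#' maximal subject to TP >= `min_tp`.
#'
#' @param scores numeric screening indices.
#' @param labels 0/1 labels parallel to scores.
#' @param cutoffs cutoff grid; the default covers [-1, 1] in steps of 0.1
#'   and includes 0.0 and 0.7.
#' @param min_tp minimum true positives a recommended cutoff must keep.
#' @return data.frame (cutoff, n_selected, TP, FP, tp_fp_ratio, EF) with a
#'   "recommended" attribute.
#' @export
chooseCutoff <- function(scores, labels,
                         cutoffs = round(seq(-1, 1, by = 0.1), 1),
                         min_tp = 1L) {
  if (!length(cutoffs)) stop("cutoff grid must be non-empty")
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1L)
  N <- length(labels)
  rows <- lapply(cutoffs, function(ct) {
    sel <- scores > ct
    tp <- sum(labels[sel] == 1L)
    fp <- sum(sel) - tp
    ratio <- if (fp == 0) (if (tp > 0) Inf else NA_real_) else tp / fp
    ef <- if (any(sel) && P > 0) (tp / sum(sel)) / (P / N) else NA_real_
    data.frame(cutoff = ct, n_selected = sum(sel), TP = tp, FP = fp,
               tp_fp_ratio = ratio, EF = ef)
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$TP >= min_tp & !is.na(tab$tp_fp_ratio))
  rec <- NA_real_
  if (length(ok)) {
    best <- max(tab$tp_fp_ratio[ok])
    rec <- max(tab$cutoff[ok][tab$tp_fp_ratio[ok] == best])
  }
  attr(tab, "recommended") <- rec
  tab
}
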