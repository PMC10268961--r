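## Cross-validation, classification metrics, Y-randomization, interaction
## matrices, diversity and descriptor-family reports.

#' Cross-validation metrics report
#'
#' @slot meanTopFilterMcc mean (over folds) of the training top-filter MCC.
#' @slot meanTop5Mcc mean (over folds) of the training top-five mean MCC.
#' @slot auc pooled test-set ROC AUC over all folds.
#' @slot tpr,tnr,fpr test-set rates at the index > 0 cutoff.
#' @slot efAtCutoff enrichment factor of the pooled top selection.
#' @slot perFold data.frame of per-fold details.
#' @export
setClass("MetricsReport",
  representation(meanTopFilterMcc = "numeric", meanTop5Mcc = "numeric",
                 auc = "numeric", tpr = "numeric", tnr = "numeric",
                 fpr = "numeric", efAtCutoff = "numeric",
                 perFold = "data.frame"))

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", nrow(object@perFold), "folds\n")
  cat(sprintf("  mean top-filter MCC %.4f (top-5 %.4f)\n",
              object@meanTopFilterMcc, object@meanTop5Mcc))
  cat(sprintf("  pooled AUC %.4f; TPR %.4f TNR %.4f FPR %.4f (index > 0)\n",
              object@auc, object@tpr, object@tnr, object@fpr))
  cat(sprintf("  EF at configured selection %.3f\n", object@efAtCutoff))
})

#' Confusion-matrix metrics
#'
#' MCC, true/false positive rate and true negative rate from raw counts,
#' with the zero-denominator convention (metric = 0, flagged).
#'
#' @param tp,fp,tn,fn non-negative integer counts, sum > 0.
#' @return list (mcc, tpr, fpr, tnr, zero_denominator = character vector of
#'   flagged metrics).
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("counts must sum to a positive total")
  flags <- character()
  prod <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (prod <= 0) { flags <- c(flags, "mcc"); 0 }
         else (tp * tn - fp * fn) / sqrt(prod)
  tpr <- if (tp + fn == 0) { flags <- c(flags, "tpr"); 0 } else tp / (tp + fn)
  fpr <- if (fp + tn == 0) { flags <- c(flags, "fpr"); 0 } else fp / (fp + tn)
  tnr <- if (fp + tn == 0) { flags <- c(flags, "tnr"); 0 } else tn / (fp + tn)
  list(mcc = mcc, tpr = tpr, fpr = fpr, tnr = tnr, zero_denominator = flags)
}

#' ROC AUC by rank statistics
#'
#' Equals the probability that a random active outranks a random decoy,
#' counting ties as one half (the Wilcoxon reading of the area under the
#' ROC curve). Accepts pooled scores concatenated over folds.
#'
#' @param scores numeric scores (higher = more active-like).
#' @param labels 0/1 labels.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  nP <- sum(labels == 1L); nN <- sum(labels == 0L)
  if (nP == 0 || nN == 0) stop("both classes are required for the AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - nP * (nP + 1) / 2) / (nP * nN)
}

#' Cross-validated model performance
#'
#' For each fold, an ISE model is built on the remaining folds and the
#' held-out fold is scored; the report carries the mean training top-filter
#' MCC across folds, the pooled test-set AUC over raw indices, TPR/TNR/FPR
#' at the index > 0 cutoff, and the enrichment factor of the pooled top
#' `ef_fraction` selection. Per-fold seeds are derived from the
#' configuration seed, so the whole procedure is deterministic.
#'
#' @param table a [DescriptorTable-class] or numeric matrix (full set).
#' @param labels 0/1 labels; a [LearningSet-class] is also accepted, in
#'   which case labels are taken from its active/decoy membership.
#' @param folds a [FoldAssignment-class] covering all rows.
#' @param config an [iseConfig()].
#' @param ef_fraction fraction of the pooled ranking used for the EF.
#' @return a [MetricsReport-class].
#' @export
crossValidate <- function(table, labels, folds, config = iseConfig(),
                          ef_fraction = 0.01) {
  X <- .tableMatrix(table)
  if (is(labels, "LearningSet")) {
    lab <- setNames(rep(c(1L, 0L), c(nrow(labels@actives),
                                     nrow(labels@decoys))),
                    c(labels@actives$id, labels@decoys$id))
    labels <- lab[rownames(X)]
  }
  labels <- .checkLabels(labels, nrow(X))
  stopifnot(is(folds, "FoldAssignment"))
  fmap <- folds@folds
  if (!all(rownames(X) %in% names(fmap)))
    stop("folds must cover every molecule in the table")
  fold <- fmap[rownames(X)]
  config <- asIseConfig(config)
  ids <- sort(unique(fold))
  pooledScore <- numeric(0)
  pooledLabel <- integer(0)
  perFold <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    f <- ids[i]
    test <- fold == f
    if (length(unique(labels[!test])) < 2L)
      stop("training folds must contain both classes (fold ", f, ")")
    if (folds@scheme == "kfold" && length(unique(labels[test])) < 2L)
      stop("fold ", f, " holds a single class")
    cfg <- config
    cfg$seed <- config$seed + i
    model <- runIse(X[!test, , drop = FALSE], labels[!test], cfg)
    sc <- screenLibrary(model, X[test, , drop = FALSE])
    pooledScore <- c(pooledScore, sc$index)
    pooledLabel <- c(pooledLabel,
                     labels[test][match(sc$molecule_id,
                                        rownames(X)[test])])
    topM <- filterMcc(model)
    perFold[[i]] <- data.frame(
      fold = f, n_train = sum(!test), n_test = sum(test),
      top_filter_mcc = topM[1],
      top5_mean_mcc = mean(head(topM, 5)),
      n_filters = length(topM))
  }
  perFold <- do.call(rbind, perFold)
  auc <- rocAuc(pooledScore, pooledLabel)
  pred <- pooledScore > 0
  tp <- sum(pred & pooledLabel == 1L); fp <- sum(pred & pooledLabel == 0L)
  fn <- sum(!pred & pooledLabel == 1L); tn <- sum(!pred & pooledLabel == 0L)
  cm <- confusionMetrics(tp, fp, tn, fn)
  ord <- order(-pooledScore, method = "radix")
  nSel <- max(1L, round(ef_fraction * length(pooledScore)))
  ef <- enrichmentFactor(pooledLabel[ord], nSel)
  new("MetricsReport",
      meanTopFilterMcc = mean(perFold$top_filter_mcc),
      meanTop5Mcc = mean(perFold$top5_mean_mcc),
      auc = auc, tpr = cm$tpr, tnr = cm$tnr, fpr = cm$fpr,
      efAtCutoff = ef, perFold = perFold)
}

#' Construct a binary interaction matrix
#'
#' @param mat 0/1 matrix with drug rownames and target colnames.
#' @param kind "reported" or "predicted".
#' @return an [InteractionMatrix-class].
#' @export
interactionMatrix <- function(mat, kind = c("reported", "predicted")) {
  kind <- match.arg(kind)
  mode(mat) <- "numeric"
  new("InteractionMatrix", mat = mat, kind = kind)
}

#' Y-randomization of an interaction matrix
#'
#' Each replicate places `n_activities` ones uniformly at random (without
#' replacement) in the matrix frame and measures the fraction landing on
#' predicted-positive cells; the mean converges to the predicted-positive
#' density of the frame. This is the null success rate against which the
#' observed prediction success is judged.
#'
#' @param predicted a predicted [InteractionMatrix-class].
#' @param n_activities number of ones to place per replicate.
#' @param n_reps replicates.
#' @param seed RNG seed.
#' @return list (mean_success, sd_success, successes).
#' @export
yRandomization <- function(predicted, n_activities, n_reps = 1000L,
                           seed = 1L) {
  stopifnot(is(predicted, "InteractionMatrix"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  cells <- length(predicted@mat)
  if (n_activities > cells)
    stop("n_activities exceeds the matrix cell count")
  hit <- as.vector(predicted@mat) == 1
  set.seed(seed)
  succ <- vapply(seq_len(n_reps), function(i)
    mean(hit[sample.int(cells, n_activities)]), numeric(1))
  list(mean_success = mean(succ), sd_success = sd(succ), successes = succ)
}

#' Compare predicted and reported interaction matrices
#'
#' Success is the percentage of reported interactions that are also
#' predicted, with per-target and per-drug breakdowns and interaction-count
#' summaries.
#'
#' @param predicted,reported [InteractionMatrix-class] objects on matching
#'   axes (same dimnames).
#' @return list (overall_success_pct, per_target, per_drug).
#' @export
compareMatrices <- function(predicted, reported) {
  stopifnot(is(predicted, "InteractionMatrix"),
            is(reported, "InteractionMatrix"))
  p <- predicted@mat; r <- reported@mat
  if (!identical(dimnames(p), dimnames(r)))
    stop("predicted and reported matrices must share drug/target axes")
  both <- p * r
  nRep <- sum(r)
  if (nRep == 0) stop("reported matrix holds no interactions")
  perTarget <- data.frame(
    target = colnames(r), reported = colSums(r), correct = colSums(both),
    predicted = colSums(p),
    success_pct = ifelse(colSums(r) > 0, 100 * colSums(both) / colSums(r),
                         NA_real_), row.names = NULL)
  perDrug <- data.frame(
    drug = rownames(r), reported = rowSums(r), correct = rowSums(both),
    predicted = rowSums(p),
    success_pct = ifelse(rowSums(r) > 0, 100 * rowSums(both) / rowSums(r),
                         NA_real_), row.names = NULL)
  list(overall_success_pct = 100 * sum(both) / nRep,
       per_target = perTarget, per_drug = perDrug)
}

.meanPairwiseTc <- function(fps) {
  n <- length(fps)
  if (n < 2) {
    warning("within-set mean Tc undefined for fewer than two fingerprints")
    return(NA_real_)
  }
  s <- 0; m <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- s + tanimoto(fps[[i]], fps[[j]]); m <- m + 1L
  }
  s / m
}

#' Diversity report from fingerprints
#'
#' Mean pairwise Tanimoto similarity within the actives, the mean over top
#' screened molecules of their maximum similarity to any active, and the
#' mean pairwise similarity within the top set. A set with mean Tc below
#' `threshold` (0.7) is flagged as diverse.
#'
#' @param active_fps list of fingerprints (integer feature sets) of actives.
#' @param top_screen_fps list of fingerprints of the top screened set.
#' @param threshold diversity flag threshold on the mean Tc.
#' @return list (tc_actives, tc_top_vs_actives, tc_top_internal,
#'   diverse_actives, diverse_top).
#' @export
diversityReport <- function(active_fps, top_screen_fps, threshold = 0.7) {
  if (!length(active_fps) || !length(top_screen_fps))
    stop("fingerprint sets must be non-empty")
  tcA <- .meanPairwiseTc(active_fps)
  tcT <- .meanPairwiseTc(top_screen_fps)
  tcX <- mean(vapply(top_screen_fps, function(fp)
    max(vapply(active_fps, function(a) tanimoto(fp, a), numeric(1))),
    numeric(1)))
  list(tc_actives = tcA, tc_top_vs_actives = tcX, tc_top_internal = tcT,
       diverse_actives = !is.na(tcA) && tcA < threshold,
       diverse_top = !is.na(tcT) && tcT < threshold)
}

#' Descriptor-family occurrence in a model
#'
#' Percentage of the model's filter slots (5 per filter) occupied by each
#' of the seven descriptor families; percentages sum to 100.
#'
#' @param model an [IseModel-class] with at least one filter.
#' @param family_map named character vector (descriptor -> family), a
#'   data.frame with columns descriptor_name/family, or NULL to use the
#'   shipped 2D-panel map.
#' @return data.frame (family, slots, pct) over all seven families.
#' @export
descriptorFamilyOccurrence <- function(model, family_map = NULL) {
  stopifnot(is(model, "IseModel"))
  if (nFilters(model) == 0) stop("model holds no filters")
  fam <- .asFamilyMap(family_map)
  slots <- as.vector(model@filters@descriptors)
  miss <- setdiff(unique(slots), names(fam))
  if (length(miss))
    stop("descriptor(s) not covered by the family map: ",
         paste(miss, collapse = ", "))
  counts <- table(factor(fam[slots], levels = DESCRIPTOR_FAMILIES))
  data.frame(family = names(counts), slots = as.integer(counts),
             pct = 100 * as.integer(counts) / length(slots),
             row.names = NULL)
}

.asFamilyMap <- function(family_map) {
  if (is.null(family_map)) return(descriptorFamilyMap())
  if (is.data.frame(family_map)) {
    stopifnot(all(c("descriptor_name", "family") %in% names(family_map)))
    return(setNames(family_map$family, family_map$descriptor_name))
  }
  stopifnot(is.character(family_map), !is.null(names(family_map)))
  family_map
}
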