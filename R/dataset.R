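## Learning-set assembly: bioactivity curation, applicability-domain decoy
## selection, cross-validation fold assignment.

.ACTIVITY_COLUMNS <- c("molecule_id", "smiles", "target_id", "activity_type",
                       "measure", "value_nM", "qualifier", "confidence",
                       "comment")

.FLAGGED_COMMENTS <- c("outside typical range", "potential transcription error")

# small structural-alert list for reactive/mutagenic flagging
.STRUCTURAL_ALERTS <- c(
  nitro = "[N+](=O)[O-]",
  acyl_halide = "C(=O)[Cl,Br,I]",
  aldehyde = "[CX3H1]=O",
  epoxide_aziridine = "[C;r3]1[O,N;r3][C;r3]1",
  azide = "N=[N+]=[N-]",
  isocyanate = "N=C=[O,S]",
  michael_acceptor = "C=C[C,S](=O)",
  alkyl_halide = "[CH2X4][Br,I]",
  anhydride = "C(=O)OC(=O)",
  peroxide = "[OX2][OX2]",
  diazo = "[N;X2]=[N;X2]"
)

#' Read bioactivity records from CSV
#'
#' Expected columns: molecule_id, smiles, target_id, activity_type
#' (agonist/antagonist), measure (EC50/IC50/Ki), value_nM (> 0), qualifier
#' (=, >, <, ~), confidence (0-9), comment. Records violating the
#' activity-type/measure pairing (agonists carry EC50; antagonists IC50 or
#' Ki) or with non-positive values are rejected with an error.
#'
#' @param path CSV file.
#' @return data.frame of validated activity records.
#' @export
readActivityCsv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.ACTIVITY_COLUMNS, names(df))
  if (length(miss))
    stop("activity CSV lacks column(s): ", paste(miss, collapse = ", "))
  stopifnot(all(df$activity_type %in% c("agonist", "antagonist")),
            all(df$measure %in% c("EC50", "IC50", "Ki")),
            all(df$qualifier %in% c("=", ">", "<", "~")),
            all(df$confidence %in% 0:9))
  if (any(df$value_nM <= 0)) stop("value_nM must be positive")
  badPair <- (df$activity_type == "agonist" & df$measure != "EC50") |
             (df$activity_type == "antagonist" &
                !df$measure %in% c("IC50", "Ki"))
  if (any(badPair))
    stop("activity-type/measure mismatch in ", sum(badPair), " record(s)")
  df
}

#' Curate activity records into a set of modeling actives
#'
#' Applies, in a fixed order, the exclusion rules used to assemble learning
#' sets: (1) flagged database comments; (2) approximate qualifiers (only
#' "=" kept); (3) weak activity above `max_value_nM`; (4) confidence not
#' above `min_confidence`; (5) ids on the exclusion list (e.g. approved
#' drugs); (6) duplicate ids collapsed keeping the worst (numerically
#' largest) value; (7) molecules matching reactive/mutagenic structural
#' alerts. Each dropped record is audited with the first applicable rule.
#'
#' @param records validated activity data.frame (single target and
#'   activity type).
#' @param exclusion_list character vector of molecule ids to exclude.
#' @param max_value_nM weak-activity threshold (default 100 uM).
#' @param min_confidence records kept when confidence is strictly above
#'   this (default 7).
#' @param highly_active_nM optional extra threshold keeping only molecules
#'   at or below it (default NULL = off).
#' @param check_alerts apply the structural-alert rule (needs SMILES
#'   parsing; set FALSE to skip).
#' @return list (kept = data.frame, audit = data.frame(molecule_id, rule,
#'   detail)).
#' @export
curateActives <- function(records, exclusion_list = character(),
                          max_value_nM = 1e5, min_confidence = 7L,
                          highly_active_nM = NULL, check_alerts = TRUE) {
  stopifnot(all(.ACTIVITY_COLUMNS %in% names(records)))
  audit <- list()
  note <- function(rows, rule, detail) {
    if (nrow(rows))
      audit[[length(audit) + 1]] <<- data.frame(
        molecule_id = rows$molecule_id, rule = rule, detail = detail,
        stringsAsFactors = FALSE)
  }
  cur <- records

  drop <- tolower(trimws(cur$comment)) %in% .FLAGGED_COMMENTS
  note(cur[drop, ], "flagged_comment", cur$comment[drop])
  cur <- cur[!drop, , drop = FALSE]

  drop <- cur$qualifier != "="
  note(cur[drop, ], "approximate_qualifier", cur$qualifier[drop])
  cur <- cur[!drop, , drop = FALSE]

  drop <- cur$value_nM > max_value_nM
  note(cur[drop, ], "weak_activity",
       sprintf("%.4g nM > %.4g nM", cur$value_nM[drop], max_value_nM))
  cur <- cur[!drop, , drop = FALSE]

  drop <- cur$confidence <= min_confidence
  note(cur[drop, ], "low_confidence", as.character(cur$confidence[drop]))
  cur <- cur[!drop, , drop = FALSE]

  drop <- cur$molecule_id %in% exclusion_list
  note(cur[drop, ], "excluded_id", "on exclusion list")
  cur <- cur[!drop, , drop = FALSE]

  if (nrow(cur)) {
    # keep the worst (largest) value per id; deterministic tie-break on order
    ord <- order(cur$molecule_id, -cur$value_nM, method = "radix")
    cur <- cur[ord, , drop = FALSE]
    dup <- duplicated(cur$molecule_id)
    note(cur[dup, ], "duplicate_collapsed",
         sprintf("worse value kept for %s", cur$molecule_id[dup]))
    cur <- cur[!dup, , drop = FALSE]
  }

  if (!is.null(highly_active_nM) && nrow(cur)) {
    drop <- cur$value_nM > highly_active_nM
    note(cur[drop, ], "not_highly_active",
         sprintf("%.4g nM > %.4g nM", cur$value_nM[drop], highly_active_nM))
    cur <- cur[!drop, , drop = FALSE]
  }

  if (check_alerts && nrow(cur)) {
    hits <- structuralAlerts(cur$smiles)
    drop <- hits$flagged
    note(cur[drop, ], "structural_alert", hits$alert[drop])
    cur <- cur[!drop, , drop = FALSE]
  }

  audit <- if (length(audit)) do.call(rbind, audit)
           else data.frame(molecule_id = character(), rule = character(),
                           detail = character(), stringsAsFactors = FALSE)
  if (!nrow(cur))
    stop(structure(class = c("iseInsufficientActives", "error", "condition"),
                   list(message = "insufficient actives: no record survived curation",
                        call = sys.call())))
  rownames(cur) <- NULL
  list(kept = cur, audit = audit)
}

#' Flag molecules matching reactive/mutagenic structural alerts
#'
#' @param smiles character vector of SMILES.
#' @return data.frame (flagged = logical, alert = first matching alert name
#'   or NA). Unparseable SMILES are flagged with alert "unparseable".
#' @export
structuralAlerts <- function(smiles) {
  flagged <- logical(length(smiles))
  alert <- rep(NA_character_, length(smiles))
  sdfs <- lapply(smiles, function(s)
    tryCatch(suppressWarnings(ChemmineR::smiles2sdf(s)),
             error = function(e) NULL))
  for (i in seq_along(smiles)) {
    if (is.null(sdfs[[i]])) { flagged[i] <- TRUE; alert[i] <- "unparseable"
    } else {
      for (a in names(.STRUCTURAL_ALERTS)) {
        n <- tryCatch(
          ChemmineR::smartsSearchOB(sdfs[[i]], .STRUCTURAL_ALERTS[[a]],
                                    uniqueMatches = TRUE),
          error = function(e) 0)
        if (any(n > 0)) { flagged[i] <- TRUE; alert[i] <- a; break }
      }
    }
  }
  data.frame(flagged = flagged, alert = alert, stringsAsFactors = FALSE)
}

#' Fit the applicability domain of a set of actives
#'
#' Mean and sample standard deviation (n - 1) of MW, clogP, HBA and HBD
#' over the actives; decoys must fall inside mean +/- 2 SD on all four.
#'
#' @param actives_props data.frame with columns MW, clogP, HBA, HBD
#'   (>= 2 rows).
#' @return an [ApplicabilityDomain-class].
#' @export
fitApplicabilityDomain <- function(actives_props) {
  miss <- setdiff(AD_PROPERTIES, names(actives_props))
  if (length(miss))
    stop("missing property column(s): ", paste(miss, collapse = ", "))
  if (nrow(actives_props) < 2)
    stop("at least two actives are required (SD undefined for one)")
  s <- sapply(AD_PROPERTIES, function(p) {
    v <- actives_props[[p]]
    if (anyNA(v)) stop("missing values in property ", p)
    c(mean = mean(v), sd = sd(v))
  })
  new("ApplicabilityDomain", stats = s)
}

#' Does each molecule fall inside the applicability domain?
#' @param props data.frame with MW, clogP, HBA, HBD columns.
#' @param ad an [ApplicabilityDomain-class].
#' @param k half-width in SDs (default 2).
#' @return logical vector.
#' @export
inApplicabilityDomain <- function(props, ad, k = 2) {
  stopifnot(is(ad, "ApplicabilityDomain"))
  ok <- rep(TRUE, nrow(props))
  for (p in AD_PROPERTIES) {
    lo <- ad@stats["mean", p] - k * ad@stats["sd", p]
    hi <- ad@stats["mean", p] + k * ad@stats["sd", p]
    ok <- ok & props[[p]] >= lo & props[[p]] <= hi
  }
  ok
}

#' Sample applicability-domain-matched decoys from a pool
#'
#' Uniform sampling without replacement among pool molecules whose MW,
#' clogP, HBA and HBD all lie inside the actives' mean +/- 2 SD box, aiming
#' for `ratio` decoys per active. A short pool returns every eligible
#' molecule with a shortfall warning rather than an error.
#'
#' @param pool data.frame (id, smiles, MW, clogP, HBA, HBD), disjoint from
#'   the actives.
#' @param ad an [ApplicabilityDomain-class].
#' @param n_actives number of actives being diluted.
#' @param ratio decoys per active (100 typical; 1000 preferred when the
#'   pool affords it).
#' @param seed RNG seed.
#' @return the sampled rows of `pool`, with attribute "shortfall" (logical).
#' @export
sampleDecoys <- function(pool, ad, n_actives, ratio = 100L, seed = 1L) {
  stopifnot(all(c("id", "smiles") %in% names(pool)),
            n_actives >= 1, ratio >= 1)
  eligible <- pool[inApplicabilityDomain(pool, ad), , drop = FALSE]
  need <- ratio * n_actives
  shortfall <- nrow(eligible) < need
  if (shortfall) {
    warning(sprintf(
      "decoy shortfall: %d eligible pool molecules for a request of %d",
      nrow(eligible), need))
    out <- eligible
  } else {
    set.seed(seed)
    out <- eligible[sample.int(nrow(eligible), need), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "shortfall") <- shortfall
  out
}

#' Assemble a learning set from curated actives and sampled decoys
#' @param actives data.frame (id, smiles).
#' @param decoys data.frame (id, smiles).
#' @param ratio requested dilution.
#' @param provenance list of curation/sampling metadata; a `shortfall`
#'   entry is set automatically when decoys fall short of ratio x actives.
#' @return a [LearningSet-class].
#' @export
learningSet <- function(actives, decoys, ratio = 100L, provenance = list()) {
  if (nrow(decoys) != ratio * nrow(actives) &&
      is.null(provenance$shortfall))
    provenance$shortfall <- TRUE
  new("LearningSet", actives = actives[, c("id", "smiles")],
      decoys = decoys[, c("id", "smiles")], ratio = as.integer(ratio),
      provenance = provenance)
}

#' Assign cross-validation folds
#'
#' Stratified k-fold when the learning set holds at least `loo_threshold`
#' actives: each class is shuffled and dealt cyclically, so each fold's
#' class counts are within one molecule of exact stratification. Below the
#' threshold, leave-one-out over the actives, with decoys dealt evenly
#' alongside.
#'
#' @param ls a [LearningSet-class], or a named 0/1 label vector
#'   (names = molecule ids, 1 = active).
#' @param k folds (>= 2; must not exceed the number of actives).
#' @param loo_threshold below this many actives, switch to LOO.
#' @param seed RNG seed.
#' @return a [FoldAssignment-class].
#' @export
assignFolds <- function(ls, k = 5L, loo_threshold = 20L, seed = 1L) {
  if (is(ls, "LearningSet")) {
    activeIds <- ls@actives$id
    decoyIds <- ls@decoys$id
  } else {
    stopifnot(!is.null(names(ls)), all(ls %in% c(0L, 1L)))
    activeIds <- names(ls)[ls == 1L]
    decoyIds <- names(ls)[ls == 0L]
  }
  nA <- length(activeIds); nD <- length(decoyIds)
  if (nA == 0 || nD == 0) stop("both actives and decoys are required")
  if (k < 2) stop("k must be at least 2")
  set.seed(seed)
  if (nA < loo_threshold) {
    scheme <- "loo"
    aFold <- seq_len(nA)
    dFold <- rep_len(seq_len(nA), nD)[sample.int(nD)]
  } else {
    if (k > nA) stop("k exceeds the number of actives")
    scheme <- "kfold"
    aFold <- rep_len(seq_len(k), nA)[sample.int(nA)]
    dFold <- rep_len(seq_len(k), nD)[sample.int(nD)]
  }
  new("FoldAssignment", scheme = scheme,
      folds = setNames(c(aFold, dFold), c(activeIds, decoyIds)))
}
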