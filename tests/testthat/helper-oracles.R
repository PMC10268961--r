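# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's compiled code paths.

# Matthews correlation from counts, plain R, zero-denominator -> 0
oracleMcc <- function(tp, fp, tn, fn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den <= 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# O(n^2) pairwise-concordance AUC with ties counted one half
oracleAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (if (p > q) 1 else if (p == q) 0.5 else 0)
  s / (length(pos) * length(neg))
}

oracleTanimoto <- function(a, b) {
  na <- length(a); nb <- length(b); nc <- length(intersect(a, b))
  if (na + nb - nc == 0) return(0)
  nc / (na + nb - nc)
}

oracleEf <- function(ranked_labels, n_selected) {
  N <- length(ranked_labels)
  P <- sum(ranked_labels == 1)
  (sum(ranked_labels[seq_len(n_selected)] == 1) / n_selected) / (P / N)
}

# Enumerate every 5-descriptor/range combination of a catalog in the same
# nested order as the package (descriptor indices ascending, ranges in
# catalog order), evaluate in plain R, and sort stably by MCC descending.
# Returns a data.frame mirroring the FilterSet columns.
oracleExhaustive <- function(catalog, X, labels) {
  X <- X[, catalog@descriptors, drop = FALSE]
  D <- length(catalog@descriptors)
  act <- labels == 1
  nAct <- sum(act); nDec <- sum(!act)
  rows <- list()
  rec <- function(start, depth, pass, descs, los, his) {
    if (depth == 5) {
      tp <- sum(pass & act); fp <- sum(pass) - tp
      rows[[length(rows) + 1]] <<- list(
        descs = descs, los = los, his = his,
        tp = tp, fp = fp, tn = nDec - fp, fn = nAct - tp,
        mcc = oracleMcc(tp, fp, nDec - fp, nAct - tp))
      return()
    }
    for (d in start:(D - (4 - depth))) {
      rt <- catalog@ranges[[d]]
      for (r in seq_len(nrow(rt))) {
        p2 <- pass & X[, d] >= rt$low[r] & X[, d] <= rt$high[r]
        rec(d + 1, depth + 1, p2, c(descs, catalog@descriptors[d]),
            c(los, rt$low[r]), c(his, rt$high[r]))
      }
    }
  }
  rec(1, 0, rep(TRUE, nrow(X)), character(), numeric(), numeric())
  mcc <- vapply(rows, `[[`, numeric(1), "mcc")
  ord <- order(-mcc, method = "radix")
  list(rows = rows[ord], mcc = mcc[ord])
}

# small labelled matrix with one planted separating 5-descriptor box
makePlantedMatrix <- function(n_act = 20, n_dec = 40, n_desc = 6,
                              seed = 1) {
  set.seed(seed)
  X <- matrix(runif(n_desc * (n_act + n_dec), 0, 100),
              ncol = n_desc,
              dimnames = list(
                sprintf("m%03d", seq_len(n_act + n_dec)),
                sprintf("D%02d", seq_len(n_desc))))
  X[seq_len(n_act), 1:5] <- matrix(runif(n_act * 5, 40, 60), ncol = 5)
  bad <- which(apply(X[-seq_len(n_act), 1:5, drop = FALSE] >= 40 &
                     X[-seq_len(n_act), 1:5, drop = FALSE] <= 60, 1, all))
  while (length(bad)) {
    X[n_act + bad, ] <- runif(length(bad) * n_desc, 0, 100)
    bad <- which(apply(X[-seq_len(n_act), 1:5, drop = FALSE] >= 40 &
                       X[-seq_len(n_act), 1:5, drop = FALSE] <= 60, 1, all))
  }
  list(X = X, labels = rep(c(1L, 0L), c(n_act, n_dec)))
}

filterSetFrame <- function(fs) {
  data.frame(mcc = fs@mcc, tp = fs@tp, fp = fs@fp, tn = fs@tn, fn = fs@fn)
}
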