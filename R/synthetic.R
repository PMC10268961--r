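## Synthetic fixtures with known ground truth: planted-box descriptor
## tables and a toy SMILES generator for end-to-end demos.

#' Generate a descriptor fixture with planted separating boxes
#'
#' Decoy descriptor values are uniform over a broad support ([0, 100] per
#' descriptor). Each planted "box" is a five-descriptor closed range of
#' width `box_width` on its own descriptor quintet; actives are drawn
#' (truncated Gaussian) inside every planted box, so each planted filter
#' separates actives from decoys perfectly, and decoys falling inside any
#' box are resampled. Label noise swaps `round(noise_rate * n_actives)`
#' active labels with as many decoy labels, preserving class sizes while
#' keeping the planted boxes the geometrically correct classifiers.
#'
#' @param n_actives,n_decoys class sizes (100 and 10000 mirror the 100:1
#'   dilution used for model building).
#' @param n_descriptors total descriptors (>= 5 * n_planted).
#' @param n_planted planted boxes (0 gives a null fixture with labels
#'   independent of the descriptors).
#' @param noise_rate label-noise rate relative to the active class.
#' @param seed RNG seed; identical seeds give identical fixtures.
#' @param box_width width of each planted range (must be smaller than the
#'   decoy support width of 100).
#' @return a [PlantedFixture-class]; its `planted` slot holds the
#'   ground-truth [IseFilter-class] boxes evaluated against the returned
#'   (possibly noisy) labels.
#' @export
generatePlantedFixture <- function(n_actives = 100L, n_decoys = 10000L,
                                   n_descriptors = 20L, n_planted = 1L,
                                   noise_rate = 0, seed = 1L,
                                   box_width = 16) {
  stopifnot(n_actives >= 1, n_decoys >= 1, n_planted >= 0,
            noise_rate >= 0, noise_rate <= 1)
  if (n_descriptors < 5 * max(n_planted, 1))
    stop("n_descriptors must be at least 5 * n_planted (and >= 5)")
  support <- c(0, 100)
  if (box_width >= diff(support))
    stop("infeasible geometry: planted box wider than the decoy support")
  set.seed(seed)
  dnames <- sprintf("D%02d", seq_len(n_descriptors))
  n <- n_actives + n_decoys
  X <- matrix(runif(n * n_descriptors, support[1], support[2]),
              nrow = n, dimnames = list(
                c(sprintf("ACT%05d", seq_len(n_actives)),
                  sprintf("DEC%05d", seq_len(n_decoys))),
                dnames))
  labels <- rep(c(1L, 0L), c(n_actives, n_decoys))

  planted <- list()
  if (n_planted > 0) {
    boxes <- vector("list", n_planted)
    for (b in seq_len(n_planted)) {
      cols <- ((b - 1) * 5 + 1):(b * 5)
      centre <- runif(5, support[1] + box_width / 2 + 10,
                      support[2] - box_width / 2 - 10)
      lo <- centre - box_width / 2
      hi <- centre + box_width / 2
      boxes[[b]] <- list(cols = cols, lo = lo, hi = hi)
      # actives: truncated Gaussian inside the box on every box descriptor
      for (j in 1:5) {
        v <- rnorm(n_actives, centre[j], box_width / 6)
        out <- v < lo[j] | v > hi[j]
        while (any(out)) {
          v[out] <- rnorm(sum(out), centre[j], box_width / 6)
          out <- v < lo[j] | v > hi[j]
        }
        X[seq_len(n_actives), cols[j]] <- v
      }
    }
    # resample decoys that fall inside any planted box
    inBox <- function(rows) {
      hit <- rep(FALSE, length(rows))
      for (bx in boxes) {
        inb <- rep(TRUE, length(rows))
        for (j in 1:5)
          inb <- inb & X[rows, bx$cols[j]] >= bx$lo[j] &
                 X[rows, bx$cols[j]] <= bx$hi[j]
        hit <- hit | inb
      }
      hit
    }
    decRows <- n_actives + seq_len(n_decoys)
    bad <- decRows[inBox(decRows)]
    while (length(bad)) {
      X[bad, ] <- runif(length(bad) * n_descriptors, support[1], support[2])
      bad <- bad[inBox(bad)]
    }
    planted <- lapply(boxes, function(bx)
      new("IseFilter",
          ranges = data.frame(descriptor = dnames[bx$cols], low = bx$lo,
                              high = bx$hi, stringsAsFactors = FALSE)))
  }

  nFlip <- round(noise_rate * n_actives)
  if (nFlip > 0) {
    flipA <- sample(seq_len(n_actives), min(nFlip, n_actives))
    flipD <- n_actives + sample(seq_len(n_decoys), min(nFlip, n_decoys))
    labels[flipA] <- 0L
    labels[flipD] <- 1L
  }

  fam <- setNames(rep_len(DESCRIPTOR_FAMILIES, n_descriptors), dnames)
  tab <- new("DescriptorTable", values = X, family = fam)
  planted <- lapply(planted, evaluateFilter, table = tab, labels = labels)
  new("PlantedFixture", table = tab, labels = labels, planted = planted,
      noiseRate = noise_rate, seed = as.integer(seed))
}

.ARYL_SUBST <- c("", "C", "CC", "OC", "F", "Cl", "C(F)(F)F", "OCC", "C#N")
.PIPERAZINE_TAIL <- c("C", "CC", "CCC", "CCc1ccccc1", "CCCc1ccccc1",
                      "CC(C)C", "CCO", "CCCC")
.DECOY_POOL <- c(
  "CCO", "CC(C)O", "CCCCO", "CC(=O)O", "CCC(=O)O", "CCCC(=O)O",
  "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
  "CC(=O)Nc1ccccc1", "c1ccncc1", "Cc1ccncc1", "c1ccc2ccccc2c1",
  "OCC(O)CO", "OCC(O)C(O)C(O)C(O)CO", "CC(N)C(=O)O", "NCC(=O)O",
  "CC(C)CC(N)C(=O)O", "OC(=O)CC(O)(CC(=O)O)C(=O)O", "CCOC(=O)C",
  "CCOCC", "C1CCOC1", "C1CCNC1", "C1CCCCC1", "CC1CCCCC1", "C1CCNCC1",
  "CN1CCCC1", "CCNCC", "CCCCN", "CCCCCC", "CCCCCCCC", "CC(C)(C)O",
  "CC(=O)C", "CCC(=O)C", "O=C1CCCCC1", "CC(O)c1ccccc1", "COc1ccccc1",
  "CCOC(=O)c1ccccc1")

#' Generate a toy SMILES demo set (arylpiperazine-like actives vs
#' small-molecule decoys)
#'
#' Actives are substituted phenylpiperazines with alkyl/arylalkyl tails — a
#' scaffold family with a receptor-ligand-like property profile (MW around
#' 200-350, a basic amine, one or two aromatic rings). Decoys are drawn
#' from a pool of small diverse fragments chosen to sit outside that
#' property box, so the two sets separate on simple 2D descriptors. The
#' output exercises the full pipeline (standardization, descriptors,
#' modeling) without any external database.
#'
#' @param n_actives,n_decoys set sizes.
#' @param seed RNG seed.
#' @param actives_path,decoys_path optional SMILES file paths to write.
#' @return list of data.frames `actives` and `decoys` (id, smiles).
#' @export
generateToySmiles <- function(n_actives = 40L, n_decoys = 80L, seed = 1L,
                              actives_path = NULL, decoys_path = NULL) {
  set.seed(seed)
  combos <- expand.grid(a = .ARYL_SUBST, b = .ARYL_SUBST,
                        t = .PIPERAZINE_TAIL, stringsAsFactors = FALSE)
  combos <- combos[sample.int(nrow(combos)), , drop = FALSE]
  mkAryl <- function(a, b) {
    p <- function(x) if (nzchar(x)) sprintf("c(%s)", x) else "c"
    # six-membered aromatic ring, substituents at two positions, the
    # ring-closure carbon carries the piperazine nitrogen
    sprintf("c1%sc%scc1", p(a), p(b))
  }
  smiA <- character(0)
  i <- 1
  while (length(smiA) < n_actives && i <= nrow(combos)) {
    s <- sprintf("%sN1CCN(%s)CC1", mkAryl(combos$a[i], combos$b[i]),
                 combos$t[i])
    if (!s %in% smiA) smiA <- c(smiA, s)
    i <- i + 1
  }
  actives <- data.frame(id = sprintf("TOYA%04d", seq_along(smiA)),
                        smiles = smiA, stringsAsFactors = FALSE)
  smiD <- rep_len(.DECOY_POOL, n_decoys)
  decoys <- data.frame(id = sprintf("TOYD%04d", seq_len(n_decoys)),
                       smiles = smiD[sample.int(n_decoys)],
                       stringsAsFactors = FALSE)
  if (!is.null(actives_path)) writeSmilesFile(actives, actives_path)
  if (!is.null(decoys_path)) writeSmilesFile(decoys, decoys_path)
  list(actives = actives, decoys = decoys)
}
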