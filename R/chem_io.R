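## Molecule I/O, standardization ("wash"), fingerprints, similarity,
## descriptor-table pruning and CSV round-trip.

.obCan <- function(smi, pH = NULL) {
  out <- tryCatch(
    if (is.null(pH))
      ChemmineOB::convertFormat("SMI", "CAN", smi)
    else
      ChemmineOB::convertFormat("SMI", "CAN", smi,
                                options = data.frame(
                                  names = "p", args = as.character(pH))),
    error = function(e) "")
  sub("[\t ].*$", "", trimws(out))
}

.recordsFrame <- function(records) {
  if (is.character(records))
    records <- data.frame(id = sprintf("M%05d", seq_along(records)),
                          smiles = records, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(records),
            all(c("id", "smiles") %in% names(records)))
  if (anyDuplicated(records$id)) stop("molecule ids must be unique")
  records
}

#' Read a SMILES file (one molecule per line, "SMILES<TAB>id")
#'
#' The id column is optional; missing ids are generated.
#'
#' @param path SMILES file.
#' @return data.frame (id, smiles).
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "[\t ]+")
  smiles <- vapply(parts, `[`, character(1), 1)
  ids <- vapply(parts, function(p)
    if (length(p) >= 2) p[2] else NA_character_, character(1))
  miss <- is.na(ids)
  ids[miss] <- sprintf("M%05d", which(miss))
  data.frame(id = ids, smiles = smiles, stringsAsFactors = FALSE)
}

#' Write a SMILES file ("SMILES<TAB>id")
#' @param records data.frame (id, smiles).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSmilesFile <- function(records, path) {
  records <- .recordsFrame(records)
  writeLines(paste(records$smiles, records$id, sep = "\t"), path)
  invisible(path)
}

#' Read molecules from an SDF file
#' @param path SDF file.
#' @return data.frame (id, smiles) of parseable entries.
#' @export
readSdfFile <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  ids <- ChemmineR::sdfid(sdfs)
  if (anyDuplicated(ids) || any(!nzchar(ids)))
    ids <- sprintf("M%05d", seq_along(sdfs))
  smi <- vapply(seq_along(sdfs), function(i) {
    out <- tryCatch(ChemmineR::sdf2smiles(sdfs[i]), error = function(e) "")
    if (length(out)) sub("[\t ].*$", "", trimws(as.character(out)[1])) else ""
  }, character(1))
  ok <- nzchar(smi)
  data.frame(id = ids[ok], smiles = smi[ok], stringsAsFactors = FALSE)
}

#' Standardize structures: strip salts, wash protonation, canonicalize
#'
#' Splits multi-component SMILES, keeps the largest organic
#' (carbon-containing) component, assigns the dominant protonation state at
#' physiological pH (aliphatic amines protonated, carboxylic acids
#' deprotonated) and emits canonical SMILES. Unparseable records are
#' returned separately with a reason; the operation is idempotent on its
#' own output.
#'
#' @param records data.frame (id, smiles) or character vector of SMILES.
#' @param pH washing pH (NULL skips the protonation step).
#' @return list with `records` (standardized data.frame, extra input columns
#'   preserved) and `rejected` (data.frame id, smiles, reason).
#' @export
standardizeStructures <- function(records, pH = 7.4) {
  records <- .recordsFrame(records)
  if (nrow(records) == 0)
    return(list(records = records,
                rejected = data.frame(id = character(), smiles = character(),
                                      reason = character())))
  outSmi <- character(nrow(records))
  reason <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    smi <- trimws(records$smiles[i])
    if (!nzchar(smi)) { reason[i] <- "empty SMILES"; next }
    comps <- strsplit(smi, ".", fixed = TRUE)[[1]]
    parsed <- vapply(comps, .obCan, character(1))
    keepable <- nzchar(parsed)
    if (!any(keepable)) { reason[i] <- "parse error"; next }
    comps <- comps[keepable]
    info <- lapply(comps, .componentInfo)
    organic <- vapply(info, `[[`, logical(1), "organic")
    if (!any(organic)) { reason[i] <- "no organic component"; next }
    heavy <- vapply(info, `[[`, integer(1), "heavy")
    heavy[!organic] <- -1L
    best <- comps[which.max(heavy)]
    washed <- .obCan(best, pH = pH)
    if (!nzchar(washed)) { reason[i] <- "wash failed"; next }
    outSmi[i] <- washed
  }
  ok <- nzchar(outSmi)
  kept <- records[ok, , drop = FALSE]
  kept$smiles <- outSmi[ok]
  rownames(kept) <- NULL
  rejected <- data.frame(id = records$id[!ok], smiles = records$smiles[!ok],
                         reason = reason[!ok], stringsAsFactors = FALSE)
  if (!nrow(kept))
    stop(structure(class = c("iseAllRejected", "error", "condition"),
                   list(message = paste0(
                     "no record survived standardization (",
                     nrow(rejected), " rejected; first reason: ",
                     rejected$reason[1], ")"), call = sys.call())))
  list(records = kept, rejected = rejected)
}

.componentInfo <- function(smi) {
  m2 <- tryCatch(ChemmineOB::convertFormat("SMI", "MOL2", smi),
                 error = function(e) "")
  at <- .parseMol2(m2)$atoms
  if (is.null(at)) return(list(organic = FALSE, heavy = 0L))
  elems <- at$element[at$element != "H"]
  list(organic = "C" %in% elems, heavy = length(elems))
}

# MOL2 text -> list(atoms = data.frame(element, type, charge),
#                   bonds = data.frame(a1, a2, type))
.parseMol2 <- function(txt) {
  if (!nzchar(txt)) return(list(atoms = NULL, bonds = NULL))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  aStart <- grep("^@<TRIPOS>ATOM", lines)
  bStart <- grep("^@<TRIPOS>BOND", lines)
  if (!length(aStart)) return(list(atoms = NULL, bonds = NULL))
  sect <- function(start) {
    if (!length(start)) return(character())
    rest <- lines[(start[1] + 1):length(lines)]
    end <- grep("^@<TRIPOS>", rest)
    if (length(end)) rest <- rest[seq_len(end[1] - 1)]
    rest[nzchar(trimws(rest))]
  }
  aLines <- sect(aStart)
  fields <- strsplit(trimws(aLines), "[[:space:]]+")
  atoms <- data.frame(
    type = vapply(fields, `[`, character(1), 6),
    charge = as.numeric(vapply(fields, `[`, character(1), 9)),
    stringsAsFactors = FALSE)
  atoms$element <- sub("\\..*$", "", atoms$type)
  bonds <- NULL
  bLines <- sect(bStart)
  if (length(bLines)) {
    bf <- strsplit(trimws(bLines), "[[:space:]]+")
    bonds <- data.frame(a1 = as.integer(vapply(bf, `[`, character(1), 2)),
                        a2 = as.integer(vapply(bf, `[`, character(1), 3)),
                        type = vapply(bf, `[`, character(1), 4),
                        stringsAsFactors = FALSE)
  }
  list(atoms = atoms, bonds = bonds)
}

#' Atom-pair fingerprint of one molecule
#'
#' Deterministic set of atom-pair feature codes; identical canonical SMILES
#' give identical bit sets.
#'
#' @param record one-row data.frame (id, smiles), a single SMILES string,
#'   or an element of a standardized record set.
#' @param scheme fingerprint scheme; "atompair" is the only one shipped.
#' @return a [Fingerprint-class].
#' @export
computeFingerprint <- function(record, scheme = "atompair") {
  scheme <- match.arg(scheme, "atompair")
  smi <- if (is.data.frame(record)) record$smiles[1] else as.character(record)
  if (is.na(smi) || !nzchar(trimws(smi))) stop("empty molecule")
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                  error = function(e) NULL)
  if (is.null(sdf)) stop("unparseable SMILES: ", smi)
  ap <- tryCatch(ChemmineR::sdf2ap(sdf[[1]]), error = function(e) NULL)
  if (is.null(ap)) stop("fingerprint computation failed for: ", smi)
  bits <- sort(unique(as.numeric(ChemmineR::ap(ap))))
  if (!length(bits) || (length(bits) == 1 && is.na(bits[1])))
    stop("no atom-pair features for: ", smi)
  new("Fingerprint", bits = bits)
}

#' Tanimoto coefficient of two fingerprints
#'
#' N_c / (N_a + N_b - N_c) over the feature sets; two empty fingerprints
#' give 0 by convention.
#'
#' @param a,b [Fingerprint-class] objects or plain feature-code vectors.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  ba <- if (is(a, "Fingerprint")) a@bits else unique(as.numeric(a))
  bb <- if (is(b, "Fingerprint")) b@bits else unique(as.numeric(b))
  na <- length(ba); nb <- length(bb)
  nc <- length(intersect(ba, bb))
  if (na + nb - nc == 0) return(0)
  nc / (na + nb - nc)
}

#' Remove constant and pairwise-correlated descriptors
#'
#' Constant columns are removed first; then, iterating columns in listed
#' order, the later member of every pair with |Pearson r| > `r_max` is
#' dropped, so the retained set has all pairwise |r| <= `r_max`. The
#' operation is deterministic and idempotent.
#'
#' @param table a [DescriptorTable-class] (>= 2 molecules).
#' @param r_max correlation threshold in (0, 1].
#' @return the pruned [DescriptorTable-class]; dropped column names are in
#'   attribute "dropped".
#' @export
pruneDescriptors <- function(table, r_max = 0.9) {
  stopifnot(is(table, "DescriptorTable"))
  if (r_max <= 0 || r_max > 1) stop("r_max must lie in (0, 1]")
  v <- table@values
  if (nrow(v) < 2) stop("pruning needs at least two molecules")
  constant <- apply(v, 2, function(x) max(x) == min(x))
  dropped <- colnames(v)[constant]
  v <- v[, !constant, drop = FALSE]
  if (ncol(v) >= 2) {
    cc <- abs(suppressWarnings(cor(v)))
    keep <- rep(TRUE, ncol(v))
    for (i in seq_len(ncol(v) - 1)) {
      if (!keep[i]) next
      for (j in (i + 1):ncol(v)) {
        if (keep[j] && !is.na(cc[i, j]) && cc[i, j] > r_max) keep[j] <- FALSE
      }
    }
    dropped <- c(dropped, colnames(v)[!keep])
    v <- v[, keep, drop = FALSE]
  }
  out <- new("DescriptorTable", values = v,
             family = table@family[colnames(v)])
  attr(out, "dropped") <- dropped
  out
}

#' Write a DescriptorTable to CSV (first column = molecule id)
#' @param table a [DescriptorTable-class].
#' @param path output CSV; the family map goes to `family_path` when given.
#' @param family_path optional CSV (descriptor_name, family).
#' @return `path`, invisibly.
#' @export
writeDescriptorCsv <- function(table, path, family_path = NULL) {
  stopifnot(is(table, "DescriptorTable"))
  df <- data.frame(molecule_id = rownames(table@values),
                   table@values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(family_path)) {
    fam <- descriptorFamilies(table)
    write.csv(data.frame(descriptor_name = names(fam), family = fam),
              family_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a DescriptorTable from CSV
#' @param path CSV with header = descriptor names, first column molecule id.
#' @param family family map: named character vector, data.frame
#'   (descriptor_name, family), path to such a CSV, or NULL for the shipped
#'   2D-panel map.
#' @return a [DescriptorTable-class].
#' @export
readDescriptorCsv <- function(path, family = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  mode(v) <- "numeric"
  rownames(v) <- as.character(df[[1]])
  if (is.character(family) && is.null(names(family)) &&
      length(family) == 1 && file.exists(family))
    family <- read.csv(family, stringsAsFactors = FALSE)
  fam <- .asFamilyMap(family)
  new("DescriptorTable", values = v, family = fam[colnames(v)])
}
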