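## Model serialization: JSON with full double precision (bit-exact
## round-trip; 17 significant digits uniquely identify a double).

.modelToList <- function(model) {
  fs <- model@filters
  filters <- lapply(seq_along(fs), function(i) {
    list(mcc = fs@mcc[i], tp = fs@tp[i], fp = fs@fp[i], tn = fs@tn[i],
         fn = fs@fn[i],
         ranges = lapply(1:5, function(j)
           list(descriptor = fs@descriptors[i, j], low = fs@lows[i, j],
                high = fs@highs[i, j])))
  })
  list(meta = list(seed = model@config$seed, config = model@config,
                   package = "isescreen"),
       weights_scheme = model@weightsScheme,
       descriptors = model@descriptors,
       filters = filters)
}

#' Write an ISE model to JSON
#'
#' Doubles are written with 17 significant digits so that
#' `readModelJson(writeModelJson(m))` reproduces the model bit-exactly and
#' re-serializing yields byte-identical files.
#'
#' @param model an [IseModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModelJson <- function(model, path) {
  stopifnot(is(model, "IseModel"))
  json <- jsonlite::toJSON(.modelToList(model), auto_unbox = TRUE,
                           digits = I(17), pretty = TRUE, null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read an ISE model from JSON
#'
#' @param path a model file written by [writeModelJson()].
#' @return an [IseModel-class].
#' @export
readModelJson <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  n <- length(x$filters)
  descs <- matrix(NA_character_, n, 5)
  lows <- matrix(NA_real_, n, 5)
  highs <- matrix(NA_real_, n, 5)
  tp <- fp <- tn <- fn <- integer(n)
  mcc <- numeric(n)
  for (i in seq_len(n)) {
    f <- x$filters[[i]]
    tp[i] <- as.integer(f$tp); fp[i] <- as.integer(f$fp)
    tn[i] <- as.integer(f$tn); fn[i] <- as.integer(f$fn)
    mcc[i] <- as.numeric(f$mcc)
    for (j in 1:5) {
      r <- f$ranges[[j]]
      descs[i, j] <- r$descriptor
      lows[i, j] <- as.numeric(r$low)
      highs[i, j] <- as.numeric(r$high)
    }
  }
  fs <- new("FilterSet", descriptors = descs, lows = lows, highs = highs,
            tp = tp, fp = fp, tn = tn, fn = fn, mcc = mcc)
  cfg <- x$meta$config
  known <- setdiff(names(formals(iseConfig)), "...")
  cfgList <- asIseConfig(cfg[intersect(names(cfg), known)])
  extra <- lapply(cfg[setdiff(names(cfg), known)], function(v)
    if (is.numeric(v) && length(v) == 1 && v == round(v) &&
        abs(v) < .Machine$integer.max) as.integer(v) else v)
  new("IseModel", filters = fs, weightsScheme = x$weights_scheme,
      config = c(unclass(cfgList), extra),
      descriptors = vapply(x$descriptors, as.character, character(1),
                           USE.NAMES = FALSE))
}
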