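#' Build an ISE run configuration
#'
#' Collects every tunable of the model-building pipeline with its default.
#' Unknown keys are rejected, so stale configuration files fail loudly.
#'
#' @param n_bins number of active-class quantile bins per descriptor from
#'   which candidate ranges (contiguous bin unions) are built.
#' @param sample_size_t filters sampled per stochastic iteration.
#' @param elim_fraction fraction of eligible ranges whose mean filter MCC
#'   marks them for elimination each iteration.
#' @param min_observations minimum times a range must be sampled before it
#'   may be eliminated.
#' @param exhaustive_threshold combination count below which the remaining
#'   catalog is enumerated exhaustively.
#' @param max_filters cap on retained filters (with `retain_fraction`, the
#'   effective cap is the smaller of the two).
#' @param retain_fraction fraction of enumerated filters retained.
#' @param min_ranges_per_descriptor floor of surviving ranges per descriptor;
#'   elimination never removes a descriptor's last ranges below it.
#' @param max_iterations safety cap on stochastic iterations.
#' @param weights_scheme filter weighting for the screening index: "unit"
#'   (+1/-1 per filter), "mcc", or "fscore".
#' @param seed integer seed controlling all stochastic steps.
#' @param ... rejected; present so misspelled arguments error.
#' @return a named list with class "iseConfig".
#' @export
iseConfig <- function(n_bins = 8L, sample_size_t = 1e5, elim_fraction = 0.2,
                      min_observations = 30L, exhaustive_threshold = 1e6,
                      max_filters = 1000L, retain_fraction = 0.2,
                      min_ranges_per_descriptor = 1L, max_iterations = 100L,
                      weights_scheme = c("unit", "mcc", "fscore"),
                      seed = 1L, ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration keys: ",
         paste(names(extra), collapse = ", "))
  weights_scheme <- match.arg(weights_scheme)
  stopifnot(n_bins >= 1, sample_size_t >= 1,
            elim_fraction >= 0, elim_fraction < 1,
            min_observations >= 1, exhaustive_threshold >= 1,
            max_filters >= 1, retain_fraction > 0, retain_fraction <= 1,
            min_ranges_per_descriptor >= 1, max_iterations >= 1)
  cfg <- list(n_bins = as.integer(n_bins), sample_size_t = sample_size_t,
              elim_fraction = elim_fraction,
              min_observations = as.integer(min_observations),
              exhaustive_threshold = exhaustive_threshold,
              max_filters = max_filters, retain_fraction = retain_fraction,
              min_ranges_per_descriptor = as.integer(min_ranges_per_descriptor),
              max_iterations = as.integer(max_iterations),
              weights_scheme = weights_scheme, seed = as.integer(seed))
  class(cfg) <- "iseConfig"
  cfg
}

#' Restore an iseConfig from a plain list (e.g. parsed JSON)
#' @param x named list of configuration values.
#' @return an "iseConfig" list with defaults filled in.
#' @export
asIseConfig <- function(x) {
  if (inherits(x, "iseConfig")) return(x)
  do.call(iseConfig, x)
}
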