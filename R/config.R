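#' Analysis configuration
#'
#' Bundles every tunable parameter of the workflow, with the package
#' defaults. All randomness in the pipeline (cross-validation folds,
#' validation splits, probability calibration) is derived from the single
#' `seed` via [derive_seed()], so a fixed configuration reproduces results
#' exactly.
#'
#' @param significance_threshold Posterior probability above which a ranked
#'   gene is flagged significant. Default 0.95.
#' @param cv_folds Number of cross-validation folds used during gene
#'   selection; capped at the smallest class size. Default 8.
#' @param cv_repeats Number of times the cross-validation is repeated with
#'   fresh fold samplings. Default 6.
#' @param max_genes_train Cap on the per-class gene count explored by forward
#'   selection. Default 100.
#' @param continue_zero_error If `TRUE`, forward selection keeps adding genes
#'   after reaching zero cross-validation error, up to `max_genes_train`.
#'   Default `FALSE`.
#' @param lp_factor The top class probability must be at least `lp_factor`
#'   times the random probability `1/K` for a sample to be assigned.
#'   Default 2.
#' @param diff_factor The gap between the two most likely classes must
#'   exceed `diff_factor` times the random probability. Default 0.8.
#' @param correlations_threshold Minimum `|r|` for a co-expression edge.
#'   Default 0.8.
#' @param interactions_threshold Minimum normalized mutual information for an
#'   interaction edge. Default 0.5.
#' @param network_top_n Number of top-ranked genes per class included in its
#'   network. Default 30.
#' @param svm_cost Soft-margin cost of the linear SVM. Default 1.
#' @param seed Integer master seed.
#'
#' @return An object of class `marker_config` (a validated list).
#' @export
#' @examples
#' cfg <- marker_config(seed = 7)
#' cfg$cv_folds
marker_config <- function(significance_threshold = 0.95,
                          cv_folds = 8L,
                          cv_repeats = 6L,
                          max_genes_train = 100L,
                          continue_zero_error = FALSE,
                          lp_factor = 2,
                          diff_factor = 0.8,
                          correlations_threshold = 0.8,
                          interactions_threshold = 0.5,
                          network_top_n = 30L,
                          svm_cost = 1,
                          seed = 42L) {
  cfg <- list(
    significance_threshold = as.numeric(significance_threshold),
    cv_folds = as.integer(cv_folds),
    cv_repeats = as.integer(cv_repeats),
    max_genes_train = as.integer(max_genes_train),
    continue_zero_error = isTRUE(continue_zero_error),
    lp_factor = as.numeric(lp_factor),
    diff_factor = as.numeric(diff_factor),
    correlations_threshold = as.numeric(correlations_threshold),
    interactions_threshold = as.numeric(interactions_threshold),
    network_top_n = as.integer(network_top_n),
    svm_cost = as.numeric(svm_cost),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$significance_threshold >= 0, cfg$significance_threshold <= 1,
    cfg$cv_folds >= 2L,
    cfg$cv_repeats >= 1L,
    cfg$max_genes_train >= 1L,
    cfg$lp_factor >= 0,
    cfg$diff_factor >= 0,
    cfg$correlations_threshold >= 0, cfg$correlations_threshold <= 1,
    cfg$interactions_threshold >= 0, cfg$interactions_threshold <= 1,
    cfg$network_top_n >= 1L,
    cfg$svm_cost > 0,
    !is.na(cfg$seed)
  )
  structure(cfg, class = "marker_config")
}

#' @export
print.marker_config <- function(x, ...) {
  cat("markerNet configuration\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Derive a stage-specific sub-seed from the master seed
#'
#' Counter-based scheme: the stage name is hashed to an integer, combined
#' with the master seed and a counter, and reduced modulo 2^31 - 1. Stages
#' therefore draw independent but reproducible random streams, and
#' reordering stages cannot silently change another stage's results.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label (e.g. `"selection"`).
#' @param index Integer counter within the stage (repeat or run number).
#' @return A positive integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage, index = 0L) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  ((abs(as.numeric(seed)) %% 2147483647) + h * 2654435 + index * 9973) %%
    2147483646 + 1
}
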