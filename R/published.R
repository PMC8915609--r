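# Published benchmark statistics shipped with the package, used as inputs for
# comparative arithmetic (RMSD deltas between datasets, percent reductions
# between models).

#' Published benchmark summary statistics
#'
#' Loads the bundled table of published evaluation statistics (RMSD, MAE,
#' regression slope, Pearson R) for the GAFF/RESP, GAFF/IPolQ-Mod and
#' GAFF/IPolQ-Mod+LJ-Fit parameter sets over the refitting and validation
#' datasets. The `subset` variant excludes iodine compounds (for the relative
#' solubility set: the haloperidol/glycerol outlier systems).
#'
#' @return A data.frame with columns `dataset`, `model`, `statistic`,
#'   `variant`, `value`.
#' @export
published_summary_stats <- function() {
  path <- system.file("extdata", "published_summary_stats.csv",
                      package = "ljrefit", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Look up one published statistic
#'
#' @param stats The table from [published_summary_stats()].
#' @param dataset,model,statistic,variant Row selectors.
#' @return The scalar value.
#' @export
published_stat <- function(stats, dataset, model, statistic, variant = "full") {
  hit <- stats$dataset == dataset & stats$model == model &
    stats$statistic == statistic & stats$variant == variant
  if (sum(hit) != 1) stop("expected exactly one row for (", dataset, ", ",
                          model, ", ", statistic, ", ", variant, ")")
  stats$value[hit]
}
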