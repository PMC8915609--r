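# Evaluation statistics (RMSD, MAE, regression slope, Pearson R, grouped
# RMSD) and the weighted RMSD-ratio objective driving the refitting.

#' Construct a reference dataset of experimental target values
#'
#' A data.frame-backed container of experimental solvation free energies and
#' liquid densities with substance-group tags, the fitting/validation target.
#'
#' @param entries A data.frame with columns `id`, `property` (`"dGsolv"` or
#'   `"density"`), `experimental`, optional `simulated`, `solute_group`,
#'   `solvent_group`, `temperature`. Units are fixed per property: kJ/mol for
#'   `dGsolv`, kg/m^3 for `density`.
#' @return The validated data.frame with class `reference_dataset`.
#' @export
reference_dataset <- function(entries) {
  stopifnot(is.data.frame(entries))
  need <- c("id", "property", "experimental")
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(entries$id)) stop("entry ids must be unique")
  if (!all(entries$property %in% c("dGsolv", "density")))
    stop("property must be 'dGsolv' or 'density'")
  for (col in c("simulated", "solute_group", "solvent_group", "temperature"))
    if (!col %in% names(entries)) entries[[col]] <- NA
  class(entries) <- c("reference_dataset", "data.frame")
  entries
}

#' Read / write a reference dataset as CSV
#' @param path File path.
#' @return A `reference_dataset` (read) or `path` invisibly (write).
#' @export
read_reference_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  reference_dataset(df)
}

#' @rdname read_reference_csv
#' @param dataset A `reference_dataset`.
#' @export
write_reference_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' RMSD and MAE of simulated vs experimental values
#'
#' @param simulated,experimental Numeric vectors of equal positive length.
#' @return Named vector `c(rmsd = , mae = )`.
#' @export
error_stats <- function(simulated, experimental) {
  if (length(simulated) == 0) stop("empty input")
  if (length(simulated) != length(experimental)) stop("length mismatch")
  d <- simulated - experimental
  if (any(!is.finite(d))) stop("non-finite values in input")
  c(rmsd = sqrt(mean(d^2)), mae = mean(abs(d)))
}

#' Regression slope (through the origin) and Pearson correlation
#'
#' The slope is the least-squares fit through the origin,
#' `m = sum(x y) / sum(x^2)` — matching the convention of reporting a single
#' slope near 1 with no intercept — while the Pearson coefficient is computed
#' on the raw (centered) pairs.
#'
#' @param simulated,experimental Numeric vectors (>= 2 pairs, nonzero
#'   variance).
#' @return Named vector `c(slope = , pearson = )`.
#' @export
regression_stats <- function(simulated, experimental) {
  if (length(simulated) < 2) stop("need at least 2 pairs")
  if (length(simulated) != length(experimental)) stop("length mismatch")
  if (var(experimental) == 0 || var(simulated) == 0)
    stop("zero variance: regression degenerate")
  c(slope = sum(experimental * simulated) / sum(experimental^2),
    pearson = cor(simulated, experimental))
}

#' RMSD aggregated by group, plus the overall value
#'
#' @param dataset A [reference_dataset()] with `simulated` filled in.
#' @param group_key Column to group by: `"solute_group"`, `"solvent_group"`,
#'   or `"temperature"` combined with `temperature_breaks`.
#' @param temperature_breaks Optional numeric breakpoints (K). Bins are
#'   lower-exclusive/upper-inclusive: a boundary temperature belongs to the
#'   lower bin.
#' @return A data.frame with columns `group`, `n`, `rmsd`; the overall RMSD is
#'   attached as attribute `"overall"` and as the last row (`group = "all"`).
#' @export
grouped_rmsd <- function(dataset, group_key = "solute_group",
                         temperature_breaks = NULL) {
  df <- as.data.frame(dataset)
  df <- df[is.finite(df$simulated) & is.finite(df$experimental), , drop = FALSE]
  if (!nrow(df)) stop("no complete simulated/experimental pairs")
  if (identical(group_key, "temperature")) {
    if (is.null(temperature_breaks)) stop("temperature grouping needs breaks")
    br <- sort(unique(c(-Inf, temperature_breaks, Inf)))
    g <- cut(df$temperature, breaks = br, right = TRUE)
  } else {
    if (!group_key %in% names(df)) stop("unknown group key '", group_key, "'")
    g <- df[[group_key]]
  }
  keep <- !is.na(g)
  if (!all(keep)) message("dropping ", sum(!keep), " entries without a '",
                          group_key, "' tag")
  df <- df[keep, , drop = FALSE]; g <- g[keep]
  groups <- split(df, droplevels(as.factor(g)))
  out <- do.call(rbind, lapply(names(groups), function(nm) {
    s <- groups[[nm]]
    data.frame(group = nm, n = nrow(s),
               rmsd = unname(error_stats(s$simulated, s$experimental)["rmsd"]))
  }))
  overall <- unname(error_stats(df$simulated, df$experimental)["rmsd"])
  out <- rbind(out, data.frame(group = "all", n = nrow(df), rmsd = overall))
  attr(out, "overall") <- overall
  out
}

#' Objective specification: weights and reference normalizers
#'
#' @param w_dG,w_rho Non-negative weights (not both zero).
#' @param rmsd_dG_ref Reference RMSD for solvation free energies, kJ/mol (> 0),
#'   from an evaluation with unaltered parameters.
#' @param rmsd_rho_ref Reference RMSD for densities, kg/m^3 (> 0).
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(w_dG = 1, w_rho = 1, rmsd_dG_ref, rmsd_rho_ref) {
  stopifnot(w_dG >= 0, w_rho >= 0)
  if (w_dG == 0 && w_rho == 0) stop("weights must not both be zero")
  if (rmsd_dG_ref <= 0 || rmsd_rho_ref <= 0)
    stop("reference RMSDs must be positive")
  structure(list(w_dG = w_dG, w_rho = w_rho, rmsd_dG_ref = rmsd_dG_ref,
                 rmsd_rho_ref = rmsd_rho_ref), class = "objective_spec")
}

#' The refitting objective: weighted sum of normalized RMSD ratios
#'
#' `Z = w_dG * rmsd_dG / rmsd_dG_ref + w_rho * rmsd_rho / rmsd_rho_ref`.
#' With both RMSDs at their unaltered-parameter reference values and unit
#' weights, Z = 2; improvements push Z below that baseline.
#'
#' @param rmsd_dG Current solvation free energy RMSD, kJ/mol.
#' @param rmsd_rho Current density RMSD, kg/m^3.
#' @param spec An [objective_spec()].
#' @return The scalar objective Z.
#' @export
objective_Z <- function(rmsd_dG, rmsd_rho, spec) {
  stopifnot(inherits(spec, "objective_spec"))
  spec$w_dG * (rmsd_dG / spec$rmsd_dG_ref) +
    spec$w_rho * (rmsd_rho / spec$rmsd_rho_ref)
}

#' Percent reduction of an error statistic relative to a baseline
#'
#' @param rmsd_baseline Baseline value (> 0).
#' @param rmsd_new New value.
#' @return `100 * (1 - rmsd_new / rmsd_baseline)` in percent.
#' @export
percent_reduction <- function(rmsd_baseline, rmsd_new) {
  if (any(rmsd_baseline <= 0)) stop("baseline must be positive")
  100 * (1 - rmsd_new / rmsd_baseline)
}

#' Full evaluation report for a dataset
#'
#' @param dataset A [reference_dataset()] with simulated values.
#' @param temperature_breaks Optional breaks (K) for the temperature-binned
#'   table.
#' @param exclude_groups Optional character vector: entries whose solute or
#'   solvent group is listed are additionally reported as an excluded-subset
#'   variant (e.g. statistics without iodine compounds).
#' @return An object of class `evaluation_report`: overall `rmsd`, `mae`,
#'   `slope`, `pearson`, per-group tables, and (when requested) the
#'   excluded-subset statistics under `$excluding`.
#' @export
evaluation_report <- function(dataset, temperature_breaks = NULL,
                              exclude_groups = NULL) {
  df <- as.data.frame(dataset)
  df <- df[is.finite(df$simulated), , drop = FALSE]
  if (!nrow(df)) stop("no simulated values to evaluate")
  es <- error_stats(df$simulated, df$experimental)
  rs <- tryCatch(regression_stats(df$simulated, df$experimental),
                 error = function(e) c(slope = NA_real_, pearson = NA_real_))
  rep_ <- list(n = nrow(df), rmsd = unname(es["rmsd"]), mae = unname(es["mae"]),
               slope = unname(rs["slope"]), pearson = unname(rs["pearson"]))
  if (any(!is.na(df$solute_group)))
    rep_$by_solute_group <- grouped_rmsd(df, "solute_group")
  if (any(!is.na(df$solvent_group)))
    rep_$by_solvent_group <- grouped_rmsd(df, "solvent_group")
  if (!is.null(temperature_breaks) && any(is.finite(df$temperature)))
    rep_$by_temperature <- grouped_rmsd(df, "temperature",
                                        temperature_breaks = temperature_breaks)
  if (!is.null(exclude_groups)) {
    keep <- !(df$solute_group %in% exclude_groups |
                df$solvent_group %in% exclude_groups)
    if (sum(keep) >= 2) {
      es2 <- error_stats(df$simulated[keep], df$experimental[keep])
      rs2 <- tryCatch(regression_stats(df$simulated[keep], df$experimental[keep]),
                      error = function(e) c(slope = NA_real_, pearson = NA_real_))
      rep_$excluding <- list(groups = exclude_groups, n = sum(keep),
                             rmsd = unname(es2["rmsd"]), mae = unname(es2["mae"]),
                             slope = unname(rs2["slope"]),
                             pearson = unname(rs2["pearson"]))
    }
  }
  structure(rep_, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> n =", x$n, "\n")
  cat(sprintf("  RMSD %.4g  MAE %.4g  slope %.4f  Pearson R %.4f\n",
              x$rmsd, x$mae, x$slope, x$pearson))
  if (!is.null(x$excluding))
    cat(sprintf("  excluding [%s]: RMSD %.4g  MAE %.4g (n = %d)\n",
                paste(x$excluding$groups, collapse = ", "),
                x$excluding$rmsd, x$excluding$mae, x$excluding$n))
  invisible(x)
}

#' Write an evaluation report as JSON
#' @param report An [evaluation_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
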