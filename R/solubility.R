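# Relative solubilities from solvation free energy differences:
# ln(c_A / c_B) = -beta (dG_A - dG_B), beta = 1/(RT).

#' A single solvation free energy record
#'
#' @param solute,solvent Names.
#' @param dG Solvation free energy, kJ/mol.
#' @param uncertainty Non-negative uncertainty, kJ/mol.
#' @param temperature Temperature in K (> 0).
#' @return An object of class `solvation_record`.
#' @export
solvation_record <- function(solute, solvent, dG, uncertainty = 0,
                             temperature = 298.15) {
  stopifnot(is.numeric(dG), is.finite(dG), uncertainty >= 0, temperature > 0)
  structure(list(solute = solute, solvent = solvent, dG = dG,
                 uncertainty = uncertainty, temperature = temperature),
            class = "solvation_record")
}

#' Relative solubility of a solute between two solvents
#'
#' The ratio of saturation concentrations follows from the solvation free
#' energy difference: `ln(c_A / c_B) = -beta (dG_A - dG_B)` with
#' `beta = 1/(RT)`. A more negative solvation free energy in A therefore means
#' higher predicted solubility in A. The uncertainty of the log-ratio is
#' propagated as `beta * sqrt(dA^2 + dB^2)`.
#'
#' @param rec_A,rec_B [solvation_record()]s for the same solute at the same
#'   temperature, in solvents A and B.
#' @return An object of class `relative_solubility` with fields `solute`,
#'   `solvent_a`, `solvent_b`, `ln_ratio`, `ratio`, `uncertainty`,
#'   `temperature`.
#' @export
relative_solubility <- function(rec_A, rec_B) {
  stopifnot(inherits(rec_A, "solvation_record"), inherits(rec_B, "solvation_record"))
  if (rec_A$solute != rec_B$solute)
    stop("records are for different solutes: ", rec_A$solute, " vs ", rec_B$solute)
  if (rec_A$temperature != rec_B$temperature)
    stop("records are at different temperatures")
  beta <- 1 / (GAS_CONSTANT * rec_A$temperature)
  ln_ratio <- -beta * (rec_A$dG - rec_B$dG)
  structure(list(solute = rec_A$solute, solvent_a = rec_A$solvent,
                 solvent_b = rec_B$solvent, ln_ratio = ln_ratio,
                 ratio = exp(ln_ratio),
                 uncertainty = beta * sqrt(rec_A$uncertainty^2 + rec_B$uncertainty^2),
                 temperature = rec_A$temperature),
            class = "relative_solubility")
}

#' All pairwise relative solubilities from a set of solvation records
#'
#' For each solute with records in n >= 2 solvents, all n(n-1)/2 unordered
#' solvent pairs are formed, oriented canonically by lexicographic solvent
#' name (A < B). Solutes with fewer than two solvents contribute nothing.
#'
#' @param records List of [solvation_record()]s.
#' @return A data.frame with one row per pair: `solute`, `solvent_a`,
#'   `solvent_b`, `ln_ratio`, `ratio`, `uncertainty`, `temperature`.
#' @export
enumerate_pairs <- function(records) {
  stopifnot(all(vapply(records, inherits, logical(1), "solvation_record")))
  solutes <- vapply(records, `[[`, character(1), "solute")
  rows <- list()
  for (s in unique(solutes)) {
    recs <- records[solutes == s]
    solvents <- vapply(recs, `[[`, character(1), "solvent")
    if (anyDuplicated(solvents))
      stop("duplicate solvent '", solvents[duplicated(solvents)][1],
           "' for solute '", s, "'")
    if (length(recs) < 2) next
    ord <- order(solvents)
    recs <- recs[ord]
    n <- length(recs)
    for (a in seq_len(n - 1)) for (b in (a + 1):n) {
      rs <- relative_solubility(recs[[a]], recs[[b]])
      rows[[length(rows) + 1L]] <- data.frame(
        solute = rs$solute, solvent_a = rs$solvent_a, solvent_b = rs$solvent_b,
        ln_ratio = rs$ln_ratio, ratio = rs$ratio,
        uncertainty = rs$uncertainty, temperature = rs$temperature)
    }
  }
  if (!length(rows))
    return(data.frame(solute = character(), solvent_a = character(),
                      solvent_b = character(), ln_ratio = numeric(),
                      ratio = numeric(), uncertainty = numeric(),
                      temperature = numeric()))
  do.call(rbind, rows)
}

#' Compare predicted relative solubilities to an experimental table
#'
#' Joins predictions to experimental log-ratios on (solute, solvent_a,
#' solvent_b) — trying both orientations of the experimental pair — and
#' returns an [evaluation_report()] on the matched ln-ratios.
#'
#' @param predicted data.frame from [enumerate_pairs()].
#' @param experimental data.frame with columns `solute`, `solvent_a`,
#'   `solvent_b`, `ln_ratio`.
#' @return An `evaluation_report` over the matched pairs.
#' @export
compare_relative_solubilities <- function(predicted, experimental) {
  key <- function(df) paste(df$solute, df$solvent_a, df$solvent_b, sep = "|")
  rkey <- function(df) paste(df$solute, df$solvent_b, df$solvent_a, sep = "|")
  pk <- key(predicted)
  m_fwd <- match(pk, key(experimental))
  m_rev <- match(pk, rkey(experimental))
  exp_val <- ifelse(!is.na(m_fwd), experimental$ln_ratio[m_fwd],
                    -experimental$ln_ratio[m_rev])
  ok <- is.finite(exp_val)
  if (!any(ok)) stop("no overlapping (solute, solvent pair) entries")
  df <- data.frame(id = pk[ok], property = "dGsolv",
                   experimental = exp_val[ok],
                   simulated = predicted$ln_ratio[ok],
                   solute_group = predicted$solute[ok])
  evaluation_report(reference_dataset(df))
}
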