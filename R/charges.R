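# Implicitly polarized charge construction (vacuum/continuum averaging) and
# mole-fraction interpolation of charges for binary mixtures. Charge sets are
# inputs from files; no quantum chemistry is performed here.

#' Construct a per-site charge set
#'
#' @param molecule Molecule name.
#' @param environment Environment label: `"vacuum"`, `"continuum:<solvent>"`,
#'   or a derived label such as `"ipolq-mod:<solvent>"`.
#' @param charges Ordered numeric vector of per-site partial charges (e).
#' @param net_charge Recorded net charge; defaults to `sum(charges)` and must
#'   agree with it within 1e-6 e.
#' @return An object of class `charge_set`.
#' @export
charge_set <- function(molecule, environment, charges, net_charge = sum(charges)) {
  stopifnot(is.character(molecule), length(molecule) == 1L)
  stopifnot(is.character(environment), length(environment) == 1L)
  stopifnot(is.numeric(charges), length(charges) >= 1L, all(is.finite(charges)))
  if (abs(net_charge - sum(charges)) > 1e-6)
    stop("recorded net charge ", net_charge, " does not match sum of charges ",
         sum(charges), " within 1e-6 e")
  structure(list(molecule = molecule, environment = environment,
                 charges = as.numeric(charges), net_charge = as.numeric(net_charge)),
            class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat("<charge_set>", x$molecule, "in", x$environment, "-",
      length(x$charges), "sites, net", format(x$net_charge), "e\n")
  invisible(x)
}

#' Average vacuum and continuum charges (implicit polarization)
#'
#' The per-site arithmetic mean of a vacuum-phase and a continuum-solvent
#' charge set, giving an implicit representation of the polarization a solute
#' experiences on transfer from vacuum into the condensed phase.
#'
#' @param q_vacuum `charge_set` with environment `"vacuum"`.
#' @param q_continuum `charge_set` with environment `"continuum:<solvent>"`.
#' @return A `charge_set` with environment `"ipolq-mod:<solvent>"`.
#' @export
ipolq_mod_average <- function(q_vacuum, q_continuum) {
  stopifnot(inherits(q_vacuum, "charge_set"), inherits(q_continuum, "charge_set"))
  if (q_vacuum$molecule != q_continuum$molecule)
    stop("charge sets are for different molecules: ",
         q_vacuum$molecule, " vs ", q_continuum$molecule)
  if (length(q_vacuum$charges) != length(q_continuum$charges))
    stop("site-count mismatch: ", length(q_vacuum$charges), " vs ",
         length(q_continuum$charges))
  if (abs(q_vacuum$net_charge - q_continuum$net_charge) > 1e-6)
    stop("net-charge mismatch beyond 1e-6 e")
  solvent <- sub("^continuum:", "", q_continuum$environment)
  charge_set(q_vacuum$molecule, paste0("ipolq-mod:", solvent),
             (q_vacuum$charges + q_continuum$charges) / 2)
}

#' Mole-fraction interpolation of charges for a binary mixture
#'
#' For compound A in a binary mixture with B, the charge of each site is the
#' linear blend `xA * q^{A,A} + (1 - xA) * q^{A,B}` of the charges derived in
#' the continuum of A itself and in the continuum of B.
#'
#' @param qAA `charge_set` of A in the continuum of A.
#' @param qAB `charge_set` of A in the continuum of B.
#' @param xA Mole fraction of A, in `[0, 1]`.
#' @return Interpolated `charge_set`.
#' @export
mixture_charges <- function(qAA, qAB, xA) {
  stopifnot(inherits(qAA, "charge_set"), inherits(qAB, "charge_set"))
  if (!is.numeric(xA) || length(xA) != 1L || is.na(xA) || xA < 0 || xA > 1)
    stop("xA must be a single mole fraction in [0, 1]")
  if (qAA$molecule != qAB$molecule)
    stop("charge sets are for different molecules")
  if (length(qAA$charges) != length(qAB$charges))
    stop("site-count mismatch")
  charge_set(qAA$molecule, sprintf("mixture:xA=%.6g", xA),
             xA * qAA$charges + (1 - xA) * qAB$charges)
}

#' Read a charge table from delimited text
#'
#' Format: header comment lines `# molecule: <name>`, `# environment: <env>`,
#' `# net_charge: <value>`, followed by whitespace-delimited columns
#' `site_index charge`.
#'
#' @param path File path.
#' @return A `charge_set`.
#' @export
read_charge_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (!length(hit)) stop("missing header '# ", key, ":' in ", path)
    trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1]))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- read.table(text = body, col.names = c("site_index", "charge"))
  df <- df[order(df$site_index), ]
  charge_set(hdr("molecule"), hdr("environment"), df$charge,
             net_charge = as.numeric(hdr("net_charge")))
}

#' Write a charge table as delimited text
#'
#' @param cs A `charge_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_charge_table <- function(cs, path) {
  stopifnot(inherits(cs, "charge_set"))
  out <- c(paste("# molecule:", cs$molecule),
           paste("# environment:", cs$environment),
           paste("# net_charge:", formatC(cs$net_charge, digits = 10, format = "g")),
           paste(seq_along(cs$charges),
                 formatC(cs$charges, digits = 10, format = "g")))
  writeLines(out, path)
  invisible(path)
}
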