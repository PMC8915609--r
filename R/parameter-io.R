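# Plain-text parameter file format.
#
#   # comment
#   [types]
#   name epsilon sigma [description...]
#   [aliases]
#   alias canonical
#   [overrides]
#   type_i type_j xi zeta
#
# Numeric values are written with 6 significant digits; write + read is the
# identity on the documented fields at that precision.

#' Read a parameter set from its plain-text format
#'
#' @param path File path.
#' @return A [parameter_set()].
#' @export
read_parameter_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  label <- "default"
  types <- list(); overrides <- list(); aliases <- character()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- tolower(gsub("\\[|\\]", "", ln))
      next
    }
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (section == "meta") {
      if (tok[1] == "label") label <- paste(tok[-1], collapse = " ")
    } else if (section == "types") {
      if (length(tok) < 3) stop("malformed [types] line: ", ln)
      nm <- tok[1]
      if (nm %in% vapply(types, `[[`, character(1), "name"))
        stop("duplicate type name '", nm, "' in ", path)
      desc <- if (length(tok) > 3) paste(tok[-(1:3)], collapse = " ") else ""
      types[[length(types) + 1L]] <-
        atom_type(nm, as.numeric(tok[2]), as.numeric(tok[3]), desc)
    } else if (section == "aliases") {
      if (length(tok) != 2) stop("malformed [aliases] line: ", ln)
      aliases[tok[1]] <- tok[2]
    } else if (section == "overrides") {
      if (length(tok) != 4) stop("malformed [overrides] line: ", ln)
      overrides[[length(overrides) + 1L]] <-
        interaction_override(tok[1], tok[2], as.numeric(tok[3]), as.numeric(tok[4]))
    } else if (nzchar(section)) {
      stop("unknown section [", section, "] in ", path)
    } else stop("content before first section in ", path, ": ", ln)
  }
  parameter_set(types, overrides, label = label, aliases = aliases)
}

#' Write a parameter set to its plain-text format
#'
#' @param ps A [parameter_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_file <- function(ps, path) {
  stopifnot(inherits(ps, "ff_parameter_set"))
  num <- function(x) formatC(x, digits = 6, format = "g")
  out <- c("# ljrefit parameter file", "[meta]", paste("label", ps$label),
           "[types]")
  for (t in ps$types)
    out <- c(out, trimws(paste(t$name, num(t$epsilon), num(t$sigma), t$description)))
  if (length(ps$aliases)) {
    out <- c(out, "[aliases]")
    for (al in names(ps$aliases)) out <- c(out, paste(al, ps$aliases[[al]]))
  }
  if (length(ps$overrides)) {
    out <- c(out, "[overrides]")
    for (o in ps$overrides)
      out <- c(out, paste(o$type_i, o$type_j, num(o$xi), num(o$zeta)))
  }
  writeLines(out, path)
  invisible(path)
}

#' Export combined pairs as a GROMACS-style nonbonded block
#'
#' Writes every type pair explicitly as a `[nonbond_params]` block (with
#' overrides applied through the combining rules) for interoperability with
#' tools that expect explicit pair parameters. Bit-exact round-tripping is not
#' promised for this export.
#'
#' @param ps A [parameter_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_gromacs_nonbond <- function(ps, path) {
  nm <- names(ps$types)
  out <- c("[ nonbond_params ]", "; i      j      func  sigma(nm)    epsilon(kJ/mol)")
  for (a in seq_along(nm)) for (b in a:length(nm)) {
    o <- find_override(ps, nm[a], nm[b])
    cp <- combine_pair(ps$types[[a]], ps$types[[b]], o)
    out <- c(out, sprintf("%-6s %-6s 1     %.6e %.6e",
                          nm[a], nm[b], cp[["sigma"]], cp[["epsilon"]]))
  }
  writeLines(out, path)
  invisible(path)
}
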