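# Molecule and system definitions for the toy simulation engine. Molecules are
# rigid: monatomic or small multi-site species with fixed internal geometry.

#' Define an interaction site
#' @param type Atom-type name (resolved against the parameter set at run time).
#' @param charge Partial charge in e.
#' @param offset Numeric length-3 position of the site in the molecule frame
#'   (nm); monatomic molecules use the origin.
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(type, charge = 0, offset = c(0, 0, 0)) {
  stopifnot(is.character(type), length(type) == 1L, nzchar(type))
  stopifnot(is.numeric(charge), length(charge) == 1L, is.finite(charge))
  stopifnot(is.numeric(offset), length(offset) == 3L, all(is.finite(offset)))
  structure(list(type = type, charge = as.numeric(charge),
                 offset = as.numeric(offset)), class = "site_spec")
}

#' Define a rigid molecule
#' @param name Molecule name.
#' @param sites List of [site_spec()] objects (or a single one).
#' @param groups Character vector of substance-group tags (used for grouped
#'   error reporting).
#' @param mass Molar mass in g/mol (required for mass densities).
#' @return An object of class `molecule_spec`.
#' @export
molecule_spec <- function(name, sites, groups = character(), mass = 50) {
  if (inherits(sites, "site_spec")) sites <- list(sites)
  stopifnot(all(vapply(sites, inherits, logical(1), "site_spec")))
  stopifnot(is.numeric(mass), mass > 0)
  structure(list(name = name, sites = sites, groups = groups,
                 mass = as.numeric(mass)), class = "molecule_spec")
}

#' Define a simulation system
#'
#' @param components List of `list(molecule = molecule_spec, count = n,
#'   role = "solvent"|"solute")` entries. At most one component may carry the
#'   solute role, and solute count must then be 1.
#' @param box_edge Cubic box edge in nm (initial edge under NPT).
#' @param temperature Temperature in K (> 0).
#' @param pressure Pressure in bar (used by NPT runs).
#' @return An object of class `system_spec`.
#' @export
system_spec <- function(components, box_edge, temperature = 300, pressure = 1) {
  stopifnot(is.list(components), length(components) >= 1L)
  stopifnot(temperature > 0, box_edge > 0)
  roles <- vapply(components, function(cc) cc$role %||% "solvent", character(1))
  counts <- vapply(components, function(cc) as.integer(cc$count %||% 1L), integer(1))
  if (any(counts < 1)) stop("component counts must be >= 1")
  if (sum(roles == "solute") > 1) stop("at most one solute component allowed")
  if (any(roles == "solute") && counts[roles == "solute"] != 1)
    stop("the solute component must have count 1")
  for (cc in components) stopifnot(inherits(cc$molecule, "molecule_spec"))
  structure(list(components = components, box_edge = as.numeric(box_edge),
                 temperature = as.numeric(temperature),
                 pressure = as.numeric(pressure)),
            class = "system_spec")
}

#' @export
print.system_spec <- function(x, ...) {
  cat("<system_spec>", x$temperature, "K,", x$pressure, "bar, box",
      x$box_edge, "nm\n")
  for (cc in x$components)
    cat("  ", cc$count %||% 1L, "x", cc$molecule$name,
        paste0("(", cc$role %||% "solvent", ")"), "\n")
  invisible(x)
}

# Expand a system + parameter set into the flat site arrays the C++ engine
# consumes. Returns 0-based mol/type indices, combined eps/sig matrices over
# the types present, total molar mass and the solute molecule index (or -1).
expand_system <- function(system, params) {
  stopifnot(inherits(system, "system_spec"), inherits(params, "ff_parameter_set"))
  type_names <- character(); mol_idx <- integer(); typ_idx <- integer()
  q <- numeric(); offsets <- matrix(0, 0, 3)
  mol_of <- integer()
  total_mass <- 0
  imol <- 0L; solute_mol <- -1L
  for (cc in system$components) {
    m <- cc$molecule; cnt <- cc$count %||% 1L
    role <- cc$role %||% "solvent"
    tn <- vapply(m$sites, function(s) resolve_type(params, s$type), character(1))
    for (t in tn) if (!t %in% type_names) type_names <- c(type_names, t)
    ti <- match(tn, type_names) - 1L
    for (k in seq_len(cnt)) {
      if (role == "solute") solute_mol <- imol
      for (s in seq_along(m$sites)) {
        mol_idx <- c(mol_idx, imol)
        typ_idx <- c(typ_idx, ti[s])
        q <- c(q, m$sites[[s]]$charge)
        offsets <- rbind(offsets, m$sites[[s]]$offset)
      }
      total_mass <- total_mass + m$mass
      imol <- imol + 1L
    }
  }
  pm <- pair_matrices(params, type_names)
  list(mol = mol_idx, typ = typ_idx, q = q, offsets = offsets,
       eps = pm$eps, sig = pm$sig, type_names = type_names,
       n_mol = imol, total_mass = total_mass, solute_mol = solute_mol)
}

# Place molecules on a simple cubic lattice (deterministic), each molecule in
# its reference orientation. Used as the initial configuration everywhere.
initial_configuration <- function(system, params) {
  ex <- expand_system(system, params)
  n <- ex$n_mol
  box <- system$box_edge
  per_side <- ceiling(n^(1 / 3))
  spacing <- box / per_side
  pos <- matrix(0, length(ex$mol), 3)
  cell <- 0L
  for (m in 0:(n - 1L)) {
    ix <- cell %% per_side
    iy <- (cell %/% per_side) %% per_side
    iz <- cell %/% (per_side * per_side)
    centre <- (c(ix, iy, iz) + 0.5) * spacing
    rows <- which(ex$mol == m)
    for (r in rows) pos[r, ] <- centre + ex$offsets[r, ]
    cell <- cell + 1L
  }
  list(positions = pos, box_edge = box, expanded = ex)
}

#' Construct a configuration object
#' @param positions N x 3 matrix of site coordinates (nm).
#' @param box_edge Cubic box edge (nm).
#' @return An object of class `mc_configuration`.
#' @export
configuration <- function(positions, box_edge) {
  stopifnot(is.matrix(positions), ncol(positions) == 3, box_edge > 0)
  structure(list(positions = positions %% box_edge, box_edge = box_edge),
            class = "mc_configuration")
}
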