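# Parameter data model: atom types, pairwise water-interaction overrides, and
# the (modified) Lorentz-Berthelot combining rules.

#' Define a Lennard-Jones atom type
#'
#' An atom type carries one (epsilon, sigma) pair shared by every atom assigned
#' to it, in the spirit of general force fields where e.g. all sp3 ring carbons
#' share a type.
#'
#' @param name Short unique identifier (e.g. `"c3R"`, `"ohP"`).
#' @param epsilon Well depth in kJ/mol; must be >= 0. Zero is legal and is how
#'   water hydrogens are excluded from dispersion interactions.
#' @param sigma Size parameter in nm; must be > 0.
#' @param description Optional free-text description.
#' @return An object of class `ff_atom_type`.
#' @export
#' @examples
#' atom_type("c3R", epsilon = 0.45, sigma = 0.34, description = "sp3 ring carbon")
atom_type <- function(name, epsilon, sigma, description = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) || epsilon < 0)
    stop("epsilon must be a single non-negative number (kJ/mol)")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("sigma must be a single positive number (nm)")
  structure(list(name = name, epsilon = as.numeric(epsilon),
                 sigma = as.numeric(sigma), description = description),
            class = "ff_atom_type")
}

#' Pairwise interaction override for the combining rules
#'
#' Dimensionless modifiers `xi` (on epsilon) and `zeta` (on sigma) applied to
#' the Lorentz-Berthelot combination of a specific type pair; in the refitting
#' workflow the second type is a water-model oxygen. `xi = zeta = 0` reproduces
#' plain Lorentz-Berthelot exactly.
#'
#' @param type_i,type_j Atom-type names; the override is symmetric in the pair.
#' @param xi Dimensionless epsilon modifier.
#' @param zeta Dimensionless sigma modifier.
#' @return An object of class `ff_override`.
#' @export
interaction_override <- function(type_i, type_j, xi = 0, zeta = 0) {
  stopifnot(is.character(type_i), is.character(type_j),
            nzchar(type_i), nzchar(type_j))
  stopifnot(is.numeric(xi), length(xi) == 1L, is.finite(xi))
  stopifnot(is.numeric(zeta), length(zeta) == 1L, is.finite(zeta))
  structure(list(type_i = type_i, type_j = type_j,
                 xi = as.numeric(xi), zeta = as.numeric(zeta)),
            class = "ff_override")
}

override_key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")

#' Assemble a force-field parameter set
#'
#' The central object being optimized: a roster of atom types plus pairwise
#' interaction overrides, with an optional alias table mapping equivalent type
#' names (types sharing nonbonded parameters) onto a canonical name.
#'
#' Validation enforces that every override references a defined type, that type
#' names are unique, and that water hydrogen types (names starting with `"hw"`)
#' carry `epsilon = 0` so they do not participate in Lennard-Jones
#' interactions.
#'
#' @param types List of [atom_type()] objects.
#' @param overrides List of [interaction_override()] objects.
#' @param label Provenance string, e.g. `"default"` or `"fit-step-7"`.
#' @param aliases Named character vector mapping alias -> canonical type name.
#' @return An object of class `ff_parameter_set`.
#' @export
parameter_set <- function(types, overrides = list(), label = "default",
                          aliases = character()) {
  if (inherits(types, "ff_atom_type")) types <- list(types)
  if (inherits(overrides, "ff_override")) overrides <- list(overrides)
  stopifnot(all(vapply(types, inherits, logical(1), "ff_atom_type")))
  stopifnot(all(vapply(overrides, inherits, logical(1), "ff_override")))
  nm <- vapply(types, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate atom type name: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  names(types) <- nm
  for (al in names(aliases))
    if (!aliases[[al]] %in% nm)
      stop("alias '", al, "' points at undefined type '", aliases[[al]], "'")
  ps <- structure(list(types = types, overrides = overrides, label = label,
                       aliases = aliases),
                  class = "ff_parameter_set")
  validate_parameter_set(ps)
  ps
}

validate_parameter_set <- function(ps) {
  nm <- names(ps$types)
  for (o in ps$overrides) {
    for (t in c(o$type_i, o$type_j))
      if (!resolvable_type(ps, t))
        stop("override references undefined atom type '", t, "'")
  }
  keys <- vapply(ps$overrides, function(o)
    override_key(resolve_type(ps, o$type_i), resolve_type(ps, o$type_j)),
    character(1))
  if (anyDuplicated(keys)) stop("duplicate override for the same type pair")
  for (t in ps$types)
    if (grepl("^hw", t$name) && t$epsilon != 0)
      stop("water hydrogen type '", t$name,
           "' must have epsilon = 0 (no Lennard-Jones interactions)")
  invisible(ps)
}

resolvable_type <- function(ps, name)
  name %in% names(ps$types) || name %in% names(ps$aliases)

#' Resolve a (possibly aliased) type name to its canonical name
#' @param ps A [parameter_set()].
#' @param name Type or alias name.
#' @return Canonical type name.
#' @export
resolve_type <- function(ps, name) {
  if (name %in% names(ps$types)) return(name)
  if (name %in% names(ps$aliases)) return(unname(ps$aliases[[name]]))
  stop("unknown atom type '", name, "'")
}

#' Look up an atom type definition
#' @inheritParams resolve_type
#' @return The `ff_atom_type` object.
#' @export
get_type <- function(ps, name) ps$types[[resolve_type(ps, name)]]

#' Replace an atom type's parameters (returns a modified copy)
#' @inheritParams resolve_type
#' @param epsilon,sigma New values; `NULL` keeps the current one.
#' @param label Optional new provenance label.
#' @return The updated `ff_parameter_set`.
#' @export
set_type_params <- function(ps, name, epsilon = NULL, sigma = NULL, label = NULL) {
  cn <- resolve_type(ps, name)
  t <- ps$types[[cn]]
  ps$types[[cn]] <- atom_type(cn, epsilon %||% t$epsilon, sigma %||% t$sigma,
                              t$description)
  if (!is.null(label)) ps$label <- label
  validate_parameter_set(ps)
  ps
}

#' Set (or replace) a pairwise interaction override
#' @inheritParams resolve_type
#' @param type_i,type_j Type pair (symmetric).
#' @param xi,zeta New modifier values.
#' @return The updated `ff_parameter_set`.
#' @export
set_override <- function(ps, type_i, type_j, xi, zeta) {
  key <- override_key(resolve_type(ps, type_i), resolve_type(ps, type_j))
  keys <- vapply(ps$overrides, function(o)
    override_key(resolve_type(ps, o$type_i), resolve_type(ps, o$type_j)),
    character(1))
  new <- interaction_override(type_i, type_j, xi, zeta)
  hit <- which(keys == key)
  if (length(hit)) ps$overrides[[hit]] <- new
  else ps$overrides[[length(ps$overrides) + 1L]] <- new
  validate_parameter_set(ps)
  ps
}

find_override <- function(ps, type_i, type_j) {
  key <- override_key(resolve_type(ps, type_i), resolve_type(ps, type_j))
  for (o in ps$overrides)
    if (override_key(resolve_type(ps, o$type_i), resolve_type(ps, o$type_j)) == key)
      return(o)
  NULL
}

#' @export
print.ff_parameter_set <- function(x, ...) {
  cat("<ff_parameter_set> label:", x$label, "\n")
  cat("  ", length(x$types), "atom types,", length(x$overrides), "overrides\n")
  for (t in x$types)
    cat(sprintf("   %-6s eps = %.6g kJ/mol  sigma = %.6g nm\n",
                t$name, t$epsilon, t$sigma))
  for (o in x$overrides)
    cat(sprintf("   %s-%s xi = %.6g zeta = %.6g\n", o$type_i, o$type_j, o$xi, o$zeta))
  invisible(x)
}

#' Lennard-Jones pair potential
#'
#' u(r) = 4 eps ((sigma/r)^12 - (sigma/r)^6). Vectorized over `r`.
#'
#' @param epsilon Well depth, kJ/mol (>= 0).
#' @param sigma Size parameter, nm (> 0).
#' @param r Interatomic distance(s), nm (> 0).
#' @return Energy in kJ/mol.
#' @export
#' @examples
#' lj_energy(0.5, 0.3, 0.3)            # 0 at r = sigma
#' lj_energy(0.5, 0.3, 2^(1/6) * 0.3)  # -epsilon at the minimum
lj_energy <- function(epsilon, sigma, r) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("r must be positive")
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(epsilon < 0)) stop("epsilon must be non-negative")
  sr6 <- (sigma / r)^6
  4 * epsilon * sr6 * (sr6 - 1)
}

#' Combine two atom types with (modified) Lorentz-Berthelot rules
#'
#' Without an override: `eps_ij = sqrt(eps_i eps_j)`, `sigma_ij =
#' (sigma_i + sigma_j)/2`. With an override the dimensionless modifiers enter
#' multiplicatively:
#' `eps_ij = (1 + xi) sqrt(eps_i eps_j)`,
#' `sigma_ij = (1 + zeta) (sigma_i + sigma_j)/2`,
#' so that `xi = zeta = 0` reproduces plain Lorentz-Berthelot exactly. The
#' convention is isolated here: an additive variant would be a one-line change.
#'
#' @param i,j [atom_type()] objects.
#' @param override An [interaction_override()] or `NULL`.
#' @return Named numeric vector `c(epsilon = , sigma = )`.
#' @export
combine_pair <- function(i, j, override = NULL) {
  stopifnot(inherits(i, "ff_atom_type"), inherits(j, "ff_atom_type"))
  eps <- sqrt(i$epsilon * j$epsilon)
  sig <- (i$sigma + j$sigma) / 2
  if (!is.null(override)) {
    stopifnot(inherits(override, "ff_override"))
    ok <- setequal(c(override$type_i, override$type_j), c(i$name, j$name)) ||
      (override$type_i == override$type_j && i$name == j$name)
    if (!ok) stop("override is for pair (", override$type_i, ", ",
                  override$type_j, "), not (", i$name, ", ", j$name, ")")
    eps <- (1 + override$xi) * eps
    sig <- (1 + override$zeta) * sig
  }
  c(epsilon = eps, sigma = sig)
}

# Combined eps/sigma matrices over the canonical types actually used; overrides
# looked up per pair. Used by the simulation engine.
pair_matrices <- function(ps, type_names) {
  k <- length(type_names)
  epsm <- matrix(0, k, k); sigm <- matrix(0.1, k, k)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    o <- find_override(ps, type_names[a], type_names[b])
    cp <- combine_pair(get_type(ps, type_names[a]), get_type(ps, type_names[b]), o)
    epsm[a, b] <- cp[["epsilon"]]; sigm[a, b] <- cp[["sigma"]]
  }
  list(eps = epsm, sig = sigm, names = type_names)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
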