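# Seeded generator of toy molecule libraries, systems and "experimental"
# reference datasets with known ground truth, so the full fit-evaluate loop is
# testable without external MD or QM software.
#
# The toy world is a noble-gas-like fluid: monatomic (plus one rigid dimer)
# species whose truth parameters are drawn from documented ranges. Pure-liquid
# state points are chosen in REDUCED units (T* = RT/eps around 0.68-0.76,
# initial rho* = 0.8) so each species sits safely in its stable liquid range
# at 1 bar; solvation state points are dense-fluid boxes of two fixed solvent
# types: a neutral reference solvent (for self-parameter tasks) and a
# designated water-like solvent (for xi/zeta water-interaction tasks).

#' Noise specification for synthetic reference data
#' @param sd_dG Gaussian noise sd on solvation free energies, kJ/mol (>= 0).
#' @param sd_rho Gaussian noise sd on densities, kg/m^3 (>= 0).
#' @param seed Seed for the noise draws.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sd_dG = 0, sd_rho = 0, seed = 1L) {
  stopifnot(sd_dG >= 0, sd_rho >= 0)
  structure(list(sd_dG = sd_dG, sd_rho = sd_rho, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Engine settings sized for the toy reference pipeline
#'
#' Defaults keep a full generate-fit-evaluate recovery run in the minutes
#' range on one CPU: short NPT runs for densities, one cached NVT solvent
#' trajectory per solvation state point, Widom insertions for the fitting
#' route.
#'
#' @param seed Master engine seed; per-system seeds are derived from it.
#' @param ... Overrides passed to [sim_settings()].
#' @return A [sim_settings()].
#' @export
toy_settings <- function(seed = 1L, ...) {
  defaults <- list(n_steps = 2000, equil_steps = 700, sample_interval = 2,
                   max_displacement = 0.09, volume_move_scale = 0.04,
                   r_cut = 1.2, n_blocks = 5, seed = seed)
  do.call(sim_settings, utils::modifyList(defaults, list(...)))
}

#' Generate a toy library with known ground truth
#'
#' Draws `n_types` atom types with truth parameters eps* in [0.2, 1.2] kJ/mol
#' and sigma* in [0.25, 0.45] nm, plus water-interaction modifiers xi*, zeta*
#' in [-0.15, 0.15] against a fixed water-like solvent type `wO`. Builds
#' pure-liquid density systems over three temperatures per type, two solvation
#' systems per type in a fixed neutral reference solvent, two water solvation
#' systems per type, and (for the last type) a rigid homonuclear dimer
#' species with its own density systems. Returns the matching interleaved
#' fit schedule (self task, then water-interaction task, per type).
#'
#' @param n_types Number of adaptable atom types (>= 1).
#' @param seed Integer seed; the library is deterministic given the seed.
#' @param n_liquid Molecule count of pure-liquid density systems.
#' @param n_solvent Solvent molecule count of solvation systems (60-150).
#' @return An object of class `toy_library`.
#' @export
build_toy_library <- function(n_types = 2, seed = 1L, n_liquid = 50,
                              n_solvent = 80) {
  stopifnot(n_types >= 1, n_solvent >= 10)
  set.seed(seed)
  tn <- paste0("t", seq_len(n_types))
  eps <- runif(n_types, 0.2, 1.2)
  sig <- runif(n_types, 0.25, 0.45)
  mass <- runif(n_types, 30, 120)
  xi <- runif(n_types, -0.15, 0.15)
  zeta <- runif(n_types, -0.15, 0.15)

  types <- lapply(seq_len(n_types), function(i)
    atom_type(tn[i], eps[i], sig[i], "adaptable toy type"))
  types <- c(types,
             list(atom_type("sR", 0.80, 0.34, "fixed reference solvent"),
                  atom_type("wO", 0.65, 0.315, "water-like oxygen"),
                  atom_type("hw", 0.0, 0.1, "water-like hydrogen (no LJ)")))
  overrides <- lapply(seq_len(n_types), function(i)
    interaction_override(tn[i], "wO", xi[i], zeta[i]))
  truth <- parameter_set(types, overrides, label = "truth")

  mols <- list()
  for (i in seq_len(n_types))
    mols[[paste0("liq_", tn[i])]] <-
      molecule_spec(paste0("liq_", tn[i]), site_spec(tn[i]),
                    groups = paste0("grp_", tn[i]), mass = mass[i])
  mols[["ref_solvent"]] <- molecule_spec("ref_solvent", site_spec("sR"),
                                         groups = "reference", mass = 40)
  mols[["water_like"]] <- molecule_spec("water_like", site_spec("wO"),
                                        groups = "water", mass = 18)
  dimer_type <- tn[n_types]
  bond <- 0.6 * sig[n_types]
  mols[["dimer"]] <- molecule_spec(
    "dimer",
    list(site_spec(dimer_type, offset = c(-bond / 2, 0, 0)),
         site_spec(dimer_type, offset = c(bond / 2, 0, 0))),
    groups = c(paste0("grp_", dimer_type), "dimers"), mass = 2 * mass[n_types])

  tstar <- c(0.68, 0.72, 0.76)
  density_systems <- list(); solv_systems <- list()
  liq_box <- function(nmol, s, rho_star, nsite = 1)
    (nmol * nsite * s^3 / rho_star)^(1 / 3)
  for (i in seq_len(n_types)) {
    for (j in seq_along(tstar)) {
      density_systems[[length(density_systems) + 1L]] <- list(
        id = sprintf("rho_%s_%d", tn[i], j), molecule = paste0("liq_", tn[i]),
        count = n_liquid, temperature = tstar[j] * eps[i] / GAS_CONSTANT,
        pressure = 1, box_edge = liq_box(n_liquid, sig[i], 0.8),
        group = paste0("grp_", tn[i]))
    }
    for (j in 1:2) {
      rho_s <- c(0.70, 0.85)[j]
      solv_systems[[length(solv_systems) + 1L]] <- list(
        id = sprintf("dg_%s_%d", tn[i], j), solute = paste0("liq_", tn[i]),
        solvent = "ref_solvent", count = n_solvent,
        temperature = 0.75 * 0.80 / GAS_CONSTANT,
        box_edge = liq_box(n_solvent, 0.34, rho_s),
        group = paste0("grp_", tn[i]))
      solv_systems[[length(solv_systems) + 1L]] <- list(
        id = sprintf("dgw_%s_%d", tn[i], j), solute = paste0("liq_", tn[i]),
        solvent = "water_like", count = n_solvent,
        temperature = 0.75 * 0.65 / GAS_CONSTANT,
        box_edge = liq_box(n_solvent, 0.315, rho_s),
        group = paste0("grp_", tn[i]))
    }
  }
  for (j in seq_along(tstar))
    density_systems[[length(density_systems) + 1L]] <- list(
      id = sprintf("rho_dimer_%d", j), molecule = "dimer", count = n_liquid %/% 2,
      temperature = tstar[j] * eps[n_types] / GAS_CONSTANT, pressure = 1,
      box_edge = liq_box(n_liquid %/% 2, sig[n_types], 0.7, nsite = 2),
      group = "dimers")

  tasks <- list()
  for (i in seq_len(n_types)) {
    self_subset <- c(sprintf("rho_%s_%d", tn[i], seq_along(tstar)),
                     sprintf("dg_%s_%d", tn[i], 1:2))
    tasks[[length(tasks) + 1L]] <- fit_task(
      tn[i], "self", subset = self_subset,
      subset_types = c(tn[i], "sR"))
    tasks[[length(tasks) + 1L]] <- fit_task(
      tn[i], "water-interaction", subset = sprintf("dgw_%s_%d", tn[i], 1:2),
      subset_types = c(tn[i], "wO"), water_type = "wO")
  }
  schedule <- adaptation_schedule(tasks, fixed_types = c("sR", "wO", "hw"))

  structure(list(truth = truth, molecules = mols,
                 density_systems = density_systems,
                 solvation_systems = solv_systems,
                 schedule = schedule, water_type = "wO",
                 fixed_types = c("sR", "wO", "hw"), seed = as.integer(seed)),
            class = "toy_library")
}

#' @export
print.toy_library <- function(x, ...) {
  cat("<toy_library>", length(x$truth$types), "types,",
      length(x$density_systems), "density systems,",
      length(x$solvation_systems), "solvation systems,",
      length(x$schedule$tasks), "fit tasks\n")
  invisible(x)
}

all_system_ids <- function(library)
  c(vapply(library$density_systems, `[[`, character(1), "id"),
    vapply(library$solvation_systems, `[[`, character(1), "id"))

seed_for_system <- function(base_seed, library, id) {
  ids <- all_system_ids(library)
  pos <- match(id, ids)
  if (is.na(pos)) stop("unknown system id '", id, "'")
  as.integer(base_seed + 131L * pos)
}

density_system_spec <- function(library, row) {
  system_spec(list(list(molecule = library$molecules[[row$molecule]],
                        count = row$count, role = "solvent")),
              box_edge = row$box_edge, temperature = row$temperature,
              pressure = row$pressure)
}

solvation_system_spec <- function(library, row, include_solute = TRUE) {
  comps <- list(list(molecule = library$molecules[[row$solvent]],
                     count = row$count, role = "solvent"))
  if (include_solute)
    comps <- c(comps, list(list(molecule = library$molecules[[row$solute]],
                                count = 1L, role = "solute")))
  system_spec(comps, box_edge = row$box_edge, temperature = row$temperature,
              pressure = 1)
}

find_system <- function(library, id) {
  for (s in library$density_systems) if (s$id == id) return(list(kind = "density", row = s))
  for (s in library$solvation_systems) if (s$id == id) return(list(kind = "dGsolv", row = s))
  stop("unknown system id '", id, "'")
}

# Cache of pure-solvent NVT trajectories for the Widom route. Solvent types
# are fixed (never fitted), so configurations are sampled once per state point
# at the library's solvent parameters and reused across the whole fit.
solvent_config_cache <- function(library, settings) {
  cache <- new.env(parent = emptyenv())
  list(
    get = function(row) {
      key <- sprintf("%s_%.6f_%.6f", row$solvent, row$temperature, row$box_edge)
      if (!exists(key, envir = cache)) {
        sys <- solvation_system_spec(library, row, include_solute = FALSE)
        st <- settings
        st$temperature <- row$temperature
        # a thinner, longer solvent trajectory: ~200 well-decorrelated
        # configurations are plenty for the Widom route and keep each
        # objective evaluation cheap
        st$n_steps <- as.integer(settings$equil_steps + 1200L)
        st$sample_interval <- 6L
        st$seed <- as.integer(settings$seed + 7L * (utf8ToInt(substr(row$solvent, 1, 1)) %% 97L) +
                                round(1000 * row$box_edge))
        assign(key, run_nvt(sys, library$truth, st, store_configs = TRUE),
               envir = cache)
      }
      get(key, envir = cache)
    })
}

# Simulate one reference system at the given parameters. Densities: NPT run
# with a system-specific seed (common random numbers across parameter sets).
# Solvation free energies: Widom insertion into the cached solvent
# configurations (smooth in the solute parameters).
simulate_reference_system <- function(library, id, params, settings, cache,
                                      n_insertions = 150) {
  fs <- find_system(library, id)
  row <- fs$row
  if (fs$kind == "density") {
    sys <- density_system_spec(library, row)
    st <- settings
    st$temperature <- row$temperature
    st$pressure <- row$pressure
    st$seed <- seed_for_system(settings$seed, library, id)
    out <- run_npt_density(sys, params, st)
    list(property = "density", value = out$density, sem = out$sem)
  } else {
    traj <- cache$get(row)
    sys <- solvation_system_spec(library, row, include_solute = FALSE)
    st <- settings
    st$temperature <- row$temperature
    out <- widom_mu_excess(traj, library$molecules[[row$solute]], sys, params,
                           st, n_insertions = n_insertions,
                           seed = seed_for_system(settings$seed, library, id))
    list(property = "dGsolv", value = out$mu_ex, sem = out$sem)
  }
}

#' Synthesize an "experimental" reference dataset from the toy library
#'
#' Runs the simulation pipeline at the library's truth parameters and adds
#' independent Gaussian noise per [noise_spec()]; the results are recorded as
#' experimental values. With zero noise the reference values equal a rerun of
#' the engine at truth parameters exactly (seeds are derived per system).
#'
#' @param library A [build_toy_library()] result.
#' @param settings Engine [sim_settings()] (see [toy_settings()]).
#' @param noise A [noise_spec()].
#' @param cache Optional solvent-configuration cache to reuse.
#' @return A [reference_dataset()] with one row per system.
#' @export
synthesize_reference <- function(library, settings = toy_settings(),
                                 noise = noise_spec(),
                                 cache = solvent_config_cache(library, settings)) {
  stopifnot(inherits(library, "toy_library"), inherits(noise, "noise_spec"))
  ids <- all_system_ids(library)
  rows <- lapply(ids, function(id) {
    sim <- tryCatch(
      simulate_reference_system(library, id, library$truth, settings, cache),
      error = function(e) stop("system '", id, "': ", conditionMessage(e)))
    fs <- find_system(library, id)
    data.frame(id = id, property = sim$property, experimental = sim$value,
               simulated = NA_real_,
               solute_group = fs$row$group,
               solvent_group = if (sim$property == "dGsolv")
                 library$molecules[[fs$row$solvent]]$groups[1] else fs$row$group,
               temperature = fs$row$temperature)
  })
  df <- do.call(rbind, rows)
  set.seed(noise$seed)
  is_dg <- df$property == "dGsolv"
  df$experimental[is_dg] <- df$experimental[is_dg] +
    rnorm(sum(is_dg), 0, noise$sd_dG)
  df$experimental[!is_dg] <- df$experimental[!is_dg] +
    rnorm(sum(!is_dg), 0, noise$sd_rho)
  reference_dataset(df)
}

#' Build the reference evaluator for [sequential_fit()]
#'
#' Returns a closure `(params, subset) -> list(rmsd_dG, rmsd_rho)` that reruns
#' the simulation pipeline (with the same per-system seeds used when the
#' reference data was synthesized) at the given parameters and compares
#' against the dataset's experimental values.
#'
#' @param library A [build_toy_library()] result.
#' @param dataset The [reference_dataset()] (typically from
#'   [synthesize_reference()]).
#' @param settings Engine settings; must match those used for the reference
#'   synthesis for the common-random-number property to hold.
#' @param cache Optional solvent-configuration cache to reuse.
#' @return The evaluator function.
#' @export
make_reference_evaluator <- function(library, dataset,
                                     settings = toy_settings(),
                                     cache = solvent_config_cache(library, settings)) {
  exp_val <- setNames(dataset$experimental, dataset$id)
  prop <- setNames(dataset$property, dataset$id)
  function(params, subset) {
    miss <- setdiff(subset, names(exp_val))
    if (length(miss)) stop("subset ids not in dataset: ", paste(miss, collapse = ", "))
    sim <- vapply(subset, function(id)
      simulate_reference_system(library, id, params, settings, cache)$value,
      numeric(1))
    p <- prop[subset]
    rmsd <- function(sel) if (!any(sel)) NA_real_ else
      unname(error_stats(sim[sel], exp_val[subset][sel])["rmsd"])
    list(rmsd_dG = rmsd(p == "dGsolv"), rmsd_rho = rmsd(p == "density"))
  }
}

#' Perturb the adaptable parameters of a library's truth set
#'
#' The standard starting point of the recovery experiment: epsilon scaled by
#' `1 + d_eps`, sigma by `1 + d_sigma` for every adaptable type; xi/zeta
#' overrides reset to `xi0`/`zeta0` (default 0, plain Lorentz-Berthelot).
#'
#' @param library A `toy_library`.
#' @param d_eps,d_sigma Relative perturbations (defaults +20 % and +5 %).
#' @param xi0,zeta0 Starting override values.
#' @return The perturbed [parameter_set()].
#' @export
perturb_truth <- function(library, d_eps = 0.2, d_sigma = 0.05,
                          xi0 = 0, zeta0 = 0) {
  ps <- library$truth
  fitted_types <- setdiff(names(ps$types), library$fixed_types)
  for (t in fitted_types) {
    tt <- ps$types[[t]]
    ps <- set_type_params(ps, t, epsilon = tt$epsilon * (1 + d_eps),
                          sigma = tt$sigma * (1 + d_sigma))
    ps <- set_override(ps, t, library$water_type, xi0, zeta0)
  }
  ps$label <- "perturbed"
  ps
}
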