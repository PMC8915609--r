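# Desk-scale Metropolis Monte Carlo: NVT/NPT sampling of rigid LJ/point-charge
# molecules in periodic cubic boxes, with analytic long-range corrections and
# block-averaged uncertainties. Replaces full MD at the scale where only
# equilibrium averages matter.

#' Simulation settings for the Monte Carlo engine
#'
#' @param temperature Temperature in K.
#' @param pressure Pressure in bar (NPT only).
#' @param n_steps Total MC sweeps (one sweep = one trial move per molecule,
#'   plus one volume-move attempt under NPT).
#' @param equil_steps Equilibration sweeps discarded before sampling.
#' @param r_cut Interaction cutoff in nm. At evaluation time the effective
#'   cutoff is `min(r_cut, 0.99 * box/2)` so the minimum-image convention
#'   stays valid in small boxes.
#' @param tail_correction Apply the analytic isotropic LJ tail correction to
#'   energy and to the work term of volume moves.
#' @param max_displacement Maximum single-molecule translation, nm.
#' @param max_rotation Maximum rigid-body rotation, rad.
#' @param volume_move_scale Half-width of ln(V) volume moves.
#' @param sample_interval Sweeps between recorded samples.
#' @param n_blocks Number of equal blocks for standard-error estimation.
#' @param seed Integer seed; every run re-seeds R's RNG so fixed settings give
#'   bit-identical trajectories.
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(temperature = 300, pressure = 1, n_steps = 5000,
                         equil_steps = 1000, r_cut = 1.2, tail_correction = TRUE,
                         max_displacement = 0.15, max_rotation = 0.4,
                         volume_move_scale = 0.05, sample_interval = 5,
                         n_blocks = 5, seed = 1L) {
  stopifnot(temperature > 0, r_cut > 0, n_steps > equil_steps, equil_steps >= 0,
            n_blocks >= 2, sample_interval >= 1)
  structure(list(temperature = temperature, pressure = pressure,
                 n_steps = as.integer(n_steps), equil_steps = as.integer(equil_steps),
                 r_cut = r_cut, tail_correction = isTRUE(tail_correction),
                 max_displacement = max_displacement, max_rotation = max_rotation,
                 volume_move_scale = volume_move_scale,
                 sample_interval = as.integer(sample_interval),
                 n_blocks = as.integer(n_blocks), seed = as.integer(seed)),
            class = "sim_settings")
}

effective_rcut <- function(r_cut, box_edge) min(r_cut, box_edge / 2 * 0.99)

#' Total potential energy of a configuration
#'
#' Pairwise LJ energies under the minimum-image convention with spherical
#' cutoff, plus the analytic isotropic tail correction if enabled, plus
#' truncated-and-shifted Coulomb for charged sites. Intramolecular pairs are
#' excluded (molecules are rigid).
#'
#' @param config An `mc_configuration` (or a list with `positions`,
#'   `box_edge`).
#' @param system A [system_spec()] matching the configuration's site layout.
#' @param params A [parameter_set()].
#' @param settings A [sim_settings()].
#' @return Energy in kJ/mol.
#' @export
total_energy <- function(config, system, params, settings) {
  ex <- expand_system(system, params)
  if (nrow(config$positions) != length(ex$mol))
    stop("configuration has ", nrow(config$positions), " sites; system expands to ",
         length(ex$mol))
  if (settings$r_cut > config$box_edge / 2)
    stop("r_cut (", settings$r_cut, " nm) exceeds half the box edge (",
         config$box_edge / 2, " nm): minimum image invalid. ",
         "Reduce r_cut or enlarge the box.")
  cpp_total_energy(config$positions, ex$mol, ex$typ, ex$q, ex$eps, ex$sig,
                   config$box_edge, settings$r_cut, settings$tail_correction)
}

run_mc_engine <- function(system, params, settings, npt, store_configs = FALSE,
                          start = NULL, smol = -1L, lambda = 1,
                          sc = softcore_spec()) {
  init <- initial_configuration(system, params)
  ex <- init$expanded
  pos <- if (is.null(start)) init$positions else start$positions
  box <- if (is.null(start)) init$box_edge else start$box_edge
  rc <- effective_rcut(settings$r_cut, box)
  set.seed(settings$seed)
  res <- cpp_run_mc(pos, ex$mol, ex$typ, ex$q, ex$eps, ex$sig, box, rc,
                    settings$tail_correction, settings$temperature,
                    settings$pressure, npt, settings$n_steps,
                    settings$equil_steps, settings$sample_interval,
                    settings$max_displacement, settings$volume_move_scale,
                    settings$max_rotation, ex$total_mass, store_configs,
                    smol, lambda, sc$alpha, sc$distance_power)
  res$expanded <- ex
  res
}

trajectory_stats <- function(res, settings) {
  structure(list(energy = res$energy, volume = res$volume, density = res$density,
                 acc_displacement = res$acc_displacement,
                 acc_volume = res$acc_volume,
                 final_pair_energy = res$final_pair_energy,
                 recomputed_pair_energy = res$recomputed_pair_energy,
                 n_blocks = settings$n_blocks),
            class = "trajectory_stats")
}

#' Standard error of the mean from equal contiguous blocks
#'
#' Splits a (possibly correlated) series into `n_blocks` equal contiguous
#' blocks and returns the standard error of the block means. Trailing samples
#' that do not fill a block are dropped.
#'
#' @param x Numeric series.
#' @param n_blocks Number of blocks (default 5).
#' @return Standard error of the mean.
#' @export
block_sem <- function(x, n_blocks = 5) {
  stopifnot(n_blocks >= 2)
  n <- length(x)
  per <- n %/% n_blocks
  if (per < 1) stop("series too short for ", n_blocks, " blocks")
  means <- vapply(seq_len(n_blocks), function(b)
    mean(x[((b - 1) * per + 1):(b * per)]), numeric(1))
  sd(means) / sqrt(n_blocks)
}

#' Run an NVT Metropolis simulation
#'
#' @inheritParams total_energy
#' @param store_configs Keep sampled configurations (needed for Widom
#'   insertion).
#' @return A `trajectory_stats` object; with `store_configs = TRUE` it also
#'   carries `configs` (samples x 3N matrix) and `config_box`.
#' @export
run_nvt <- function(system, params, settings, store_configs = FALSE) {
  res <- run_mc_engine(system, params, settings, npt = FALSE,
                       store_configs = store_configs)
  st <- trajectory_stats(res, settings)
  if (store_configs) { st$configs <- res$configs; st$config_box <- res$config_box }
  st$expanded <- res$expanded
  st
}

#' Run an NPT simulation and estimate the liquid mass density
#'
#' Particle moves plus volume moves in ln(V) with the standard (N+1)-Jacobian
#' acceptance weight. The density estimate is the production average of the
#' instantaneous mass density m/V (the estimator used by standard MD analysis
#' tools, and unbiased for an ideal gas, unlike m/<V>); its uncertainty is the
#' standard error over `n_blocks` equal blocks.
#'
#' @inheritParams run_nvt
#' @return List with `density` (kg/m^3), `sem` (kg/m^3) and `stats`
#'   (`trajectory_stats`).
#' @export
run_npt_density <- function(system, params, settings, store_configs = FALSE) {
  stopifnot(settings$pressure > 0)
  res <- run_mc_engine(system, params, settings, npt = TRUE,
                       store_configs = store_configs)
  if (!length(res$density)) stop("no production samples recorded")
  st <- trajectory_stats(res, settings)
  if (store_configs) { st$configs <- res$configs; st$config_box <- res$config_box }
  list(density = mean(res$density),
       sem = block_sem(res$density, settings$n_blocks),
       stats = st)
}

#' Excess chemical potential by Widom test-particle insertion
#'
#' Inserts a ghost copy of the solute molecule at random positions and
#' orientations into stored solvent configurations and returns
#' `mu_ex = -RT log < exp(-beta dU) >`. Serves as an independent route to the
#' solvation free energy for cross-checking the alchemical pathway.
#'
#' @param stats A `trajectory_stats` carrying stored configurations (from
#'   [run_nvt()] or [run_npt_density()] with `store_configs = TRUE`).
#' @param solute A [molecule_spec()] to insert.
#' @param system The [system_spec()] the configurations were sampled from.
#' @param params A [parameter_set()].
#' @param settings A [sim_settings()]; temperature, cutoff and block count are
#'   used.
#' @param n_insertions Trial insertions per stored configuration.
#' @param seed Seed for the insertion RNG.
#' @return List with `mu_ex` (kJ/mol), `sem` (kJ/mol, from block averages of
#'   the insertion weights) and `n_insertions`.
#' @export
widom_mu_excess <- function(stats, solute, system, params, settings,
                            n_insertions = 200, seed = settings$seed + 1L) {
  if (is.null(stats$configs) || nrow(stats$configs) == 0)
    stop("no stored configurations: rerun with store_configs = TRUE")
  stopifnot(inherits(solute, "molecule_spec"))
  ex <- expand_system(system, params)
  all_types <- ex$type_names
  sol_tn <- vapply(solute$sites, function(s) resolve_type(params, s$type), character(1))
  for (t in sol_tn) if (!t %in% all_types) all_types <- c(all_types, t)
  pm <- pair_matrices(params, all_types)
  sol_typ <- match(sol_tn, all_types) - 1L
  sol_off <- do.call(rbind, lapply(solute$sites, `[[`, "offset"))
  sol_q <- vapply(solute$sites, `[[`, numeric(1), "charge")
  beta <- 1 / (GAS_CONSTANT * settings$temperature)
  set.seed(seed)
  w <- cpp_widom(stats$configs, stats$config_box, ex$typ, ex$q, pm$eps, pm$sig,
                 settings$r_cut, sol_off, sol_typ, sol_q,
                 as.integer(n_insertions), beta)
  mu <- -log(mean(w)) / beta
  nb <- settings$n_blocks
  per <- length(w) %/% nb
  bm <- vapply(seq_len(nb), function(b) mean(w[((b - 1) * per + 1):(b * per)]),
               numeric(1))
  sem_w <- sd(bm) / sqrt(nb)
  list(mu_ex = mu, sem = sem_w / (beta * mean(w)), n_insertions = n_insertions)
}
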