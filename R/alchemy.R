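# Alchemical solvation free energies: a 1-1-48 softcore decoupling pathway,
# multi-state sampling of solute-solvent interactions, and lambda-schedule
# redistribution toward equal per-interval uncertainties.

#' Softcore specification (1-1-48 by default)
#'
#' @param alpha Softcore parameter (default 0.003).
#' @param lambda_power Power of lambda in the energy prefactor (default 1).
#' @param one_minus_lambda_power Power of (1 - lambda) inside the distance
#'   remapping (default 1).
#' @param distance_power Distance power of the remapping (default 48).
#' @return An object of class `softcore_spec`.
#' @export
softcore_spec <- function(alpha = 0.003, lambda_power = 1L,
                          one_minus_lambda_power = 1L, distance_power = 48L) {
  stopifnot(alpha >= 0, lambda_power >= 1, one_minus_lambda_power >= 1,
            distance_power >= 1)
  structure(list(alpha = alpha, lambda_power = as.integer(lambda_power),
                 one_minus_lambda_power = as.integer(one_minus_lambda_power),
                 distance_power = as.integer(distance_power)),
            class = "softcore_spec")
}

#' Softcore Lennard-Jones interaction
#'
#' Beutler-family softcore with the 1-1-48 parameterization: the pair distance
#' is remapped to `r_sc = (alpha sigma^p (1-lambda)^b + r^p)^(1/p)` with
#' `p = distance_power` and `b = one_minus_lambda_power`, and the energy is
#' `lambda^a * lj_energy(eps, sigma, r_sc)` with `a = lambda_power`. At
#' `lambda = 1` this reduces exactly to [lj_energy()]; at `lambda = 0` it is
#' identically zero; for `lambda < 1` it stays finite down to zero distance.
#'
#' @param epsilon Well depth, kJ/mol.
#' @param sigma Size parameter, nm.
#' @param r Distance, nm (>= 0; vectorized).
#' @param lambda Coupling variable in `[0, 1]` (1 = fully coupled).
#' @param spec A [softcore_spec()].
#' @return Energy in kJ/mol.
#' @export
softcore_lj <- function(epsilon, sigma, r, lambda, spec = softcore_spec()) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1)
    stop("lambda must lie in [0, 1]")
  stopifnot(all(r >= 0), sigma > 0, epsilon >= 0)
  if (lambda == 0) return(rep(0, length(r)))
  p <- spec$distance_power
  rsc_p <- spec$alpha * sigma^p * (1 - lambda)^spec$one_minus_lambda_power + r^p
  if (lambda == 1) {
    u <- lj_energy(epsilon, sigma, pmax(r, .Machine$double.xmin))
    return(u)
  }
  rsc <- rsc_p^(1 / p)
  lambda^spec$lambda_power * lj_energy(epsilon, sigma, rsc)
}

#' Construct a lambda schedule
#'
#' @param values Strictly increasing values in `[0, 1]` with endpoints exactly
#'   0 and 1. `lambda = 0` is the decoupled state, `lambda = 1` fully coupled.
#' @return An object of class `lambda_schedule`.
#' @export
lambda_schedule <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("a lambda schedule needs at least 2 states")
  if (values[1] != 0 || values[length(values)] != 1)
    stop("lambda schedule endpoints must be exactly 0 and 1")
  if (any(diff(values) <= 0)) stop("lambda values must be strictly increasing")
  structure(list(values = values), class = "lambda_schedule")
}

#' Evenly spaced lambda schedule with K states
#' @param k Number of states (>= 2).
#' @return A [lambda_schedule()].
#' @export
uniform_schedule <- function(k) lambda_schedule(seq(0, 1, length.out = k))

#' Sample the alchemical pathway
#'
#' Runs one equilibrated NVT Monte Carlo simulation per lambda-state in which
#' only solute-solvent interactions are scaled (LJ through the softcore,
#' solute charges linearly). Every recorded configuration is re-evaluated at
#' all K states, yielding the reduced potential matrix MBAR consumes. Only the
#' solute-solvent term enters the reduced potentials; the solvent-solvent
#' energy is common to all states and cancels in free-energy differences.
#'
#' @param system A [system_spec()] with exactly one solute component.
#' @param params A [parameter_set()].
#' @param schedule A [lambda_schedule()] with K >= 2 states.
#' @param settings A [sim_settings()]; per-state seeds are derived from
#'   `settings$seed`.
#' @param spec A [softcore_spec()].
#' @return An object of class `reduced_potential_matrix`: list with `u_kn`
#'   (K x N dimensionless), `n_k`, `schedule`, `beta`.
#' @export
sample_alchemical <- function(system, params, schedule, settings,
                              spec = softcore_spec()) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  lam <- schedule$values
  if (length(lam) < 2) stop("schedule must have at least 2 states")
  ex0 <- expand_system(system, params)
  if (ex0$solute_mol < 0) stop("system has no solute component")
  beta <- 1 / (GAS_CONSTANT * settings$temperature)
  u_blocks <- list(); n_k <- integer(length(lam))
  for (k in seq_along(lam)) {
    st_k <- settings
    st_k$seed <- settings$seed + 1000L * k
    res <- run_mc_engine(system, params, st_k, npt = FALSE, store_configs = TRUE,
                         smol = ex0$solute_mol, lambda = lam[k], sc = spec)
    uk <- cpp_eval_lambda_energies(res$configs, res$config_box, ex0$mol, ex0$typ,
                                   ex0$q, ex0$eps, ex0$sig,
                                   effective_rcut(settings$r_cut, system$box_edge),
                                   ex0$solute_mol, lam, spec$alpha,
                                   spec$distance_power)
    u_blocks[[k]] <- uk
    n_k[k] <- ncol(uk)
  }
  u_kn <- do.call(cbind, u_blocks) * beta
  reduced_potential_matrix(u_kn, n_k, schedule = schedule, beta = beta)
}

#' Construct a reduced-potential matrix container
#' @param u_kn K x N matrix of reduced potentials (beta * U, dimensionless):
#'   all N samples evaluated at each of the K states.
#' @param n_k Integer vector: samples drawn from each state; must sum to N.
#' @param schedule Optional [lambda_schedule()] provenance.
#' @param beta Optional inverse temperature (1/(kJ/mol)).
#' @return An object of class `reduced_potential_matrix`.
#' @export
reduced_potential_matrix <- function(u_kn, n_k, schedule = NULL, beta = NULL) {
  stopifnot(is.matrix(u_kn), all(is.finite(u_kn)))
  n_k <- as.integer(n_k)
  if (length(n_k) != nrow(u_kn)) stop("length(n_k) must equal nrow(u_kn)")
  if (sum(n_k) != ncol(u_kn)) stop("sum(n_k) must equal ncol(u_kn)")
  structure(list(u_kn = u_kn, n_k = n_k, schedule = schedule, beta = beta),
            class = "reduced_potential_matrix")
}

#' Serialize / deserialize a reduced-potential matrix
#'
#' The matrix itself is written as whitespace-delimited text and the metadata
#' (`n_k`, lambda schedule, `beta`) as a JSON sidecar `<path>.json`, so the
#' estimator can be re-run without re-simulation.
#'
#' @param rpm A [reduced_potential_matrix()].
#' @param path Base file path.
#' @return `path` invisibly (write) or the restored object (read).
#' @export
write_rpm <- function(rpm, path) {
  stopifnot(inherits(rpm, "reduced_potential_matrix"))
  write.table(rpm$u_kn, path, row.names = FALSE, col.names = FALSE)
  meta <- list(n_k = rpm$n_k, beta = rpm$beta,
               lambda = if (!is.null(rpm$schedule)) rpm$schedule$values)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rpm
#' @export
read_rpm <- function(path) {
  u <- as.matrix(read.table(path, header = FALSE))
  dimnames(u) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  reduced_potential_matrix(u, meta$n_k,
                           schedule = if (!is.null(meta$lambda))
                             lambda_schedule(meta$lambda),
                           beta = meta$beta)
}

#' Redistribute lambda states toward equal per-interval uncertainties
#'
#' Builds the cumulative uncertainty profile over the current schedule
#' (piecewise linear in lambda), then places the same number of interior
#' points at equal increments of cumulative uncertainty. Endpoints stay
#' exactly 0 and 1; an already-equal profile is a fixed point.
#'
#' @param schedule A [lambda_schedule()] with K states.
#' @param per_interval_uncertainties Positive uncertainties, one per interval
#'   (length K - 1).
#' @return A new [lambda_schedule()] with the same K.
#' @export
redistribute_lambdas <- function(schedule, per_interval_uncertainties) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  d <- as.numeric(per_interval_uncertainties)
  lam <- schedule$values
  if (length(d) != length(lam) - 1)
    stop("need one uncertainty per interval (", length(lam) - 1, ")")
  if (any(!is.finite(d)) || any(d <= 0)) stop("uncertainties must be positive")
  cum <- c(0, cumsum(d))
  targets <- seq(0, cum[length(cum)], length.out = length(lam))
  new_lam <- approx(x = cum, y = lam, xout = targets, ties = "ordered")$y
  new_lam[1] <- 0; new_lam[length(new_lam)] <- 1
  # guard against ties from flat cumulative stretches
  for (i in 2:length(new_lam))
    if (new_lam[i] <= new_lam[i - 1])
      new_lam[i] <- new_lam[i - 1] + 1e-12
  new_lam[length(new_lam)] <- 1
  lambda_schedule(new_lam)
}

#' Alchemical solvation free energy
#'
#' Full workflow: `n_trial_rounds` short trial simulations that adjust the
#' lambda schedule toward equal per-interval uncertainties, followed by a
#' production run and MBAR estimation. The sign convention is
#' `dG_solv = G(coupled) - G(decoupled)`: negative for favorable solvation.
#'
#' @inheritParams sample_alchemical
#' @param n_trial_rounds Schedule-adjustment rounds before production
#'   (default 3).
#' @param trial_fraction Length of each trial run relative to production.
#' @param bootstrap_B If > 0, replace the asymptotic uncertainty by a bootstrap
#'   standard deviation over `bootstrap_B` resamples.
#' @return A `free_energy_result` (see [mbar_estimate()]); the final schedule
#'   is attached as `$schedule`.
#' @export
solvation_free_energy <- function(system, params, schedule, settings,
                                  n_trial_rounds = 3, trial_fraction = 0.25,
                                  spec = softcore_spec(), bootstrap_B = 0) {
  temperature <- settings$temperature
  sched <- schedule
  if (n_trial_rounds > 0) {
    trial_settings <- settings
    trial_settings$n_steps <- max(settings$equil_steps + 10L * settings$sample_interval,
                                  as.integer(settings$n_steps * trial_fraction))
    for (round in seq_len(n_trial_rounds)) {
      trial_settings$seed <- settings$seed + 77L * round
      rpm <- sample_alchemical(system, params, sched, trial_settings, spec)
      est <- mbar_estimate(rpm, temperature = temperature)
      unc <- pmax(est$per_interval$uncertainty, 1e-8)
      sched <- redistribute_lambdas(sched, unc)
    }
  }
  rpm <- sample_alchemical(system, params, sched, settings, spec)
  est <- mbar_estimate(rpm, temperature = temperature)
  if (bootstrap_B > 0)
    est$uncertainty <- bootstrap_dG(rpm, B = bootstrap_B,
                                    seed = settings$seed + 4242L,
                                    temperature = temperature)
  est$schedule <- sched
  est
}
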