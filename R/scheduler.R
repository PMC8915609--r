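# Sequential atom-type adaptation: fit tasks, the prerequisite-checked
# schedule, and the driver that optimizes one atom type at a time while
# earlier results stay frozen.

#' Define one fitting task
#'
#' A task optimizes either the self parameters (epsilon, sigma) of one atom
#' type or its water-interaction modifiers (xi, zeta) against a subset of the
#' reference data.
#'
#' @param type Target atom-type name.
#' @param kind `"self"` (fit epsilon and sigma) or `"water-interaction"` (fit
#'   the xi/zeta override against `water_type`).
#' @param subset Character vector of reference-system ids the task is fitted
#'   against (nonempty).
#' @param subset_types Atom types occurring in the subset's molecules; used to
#'   validate the prerequisite ordering (every non-fixed type must already be
#'   optimized when the task runs).
#' @param water_type Water oxygen type name for `"water-interaction"` tasks.
#' @param w_dG,w_rho Objective weights for this task.
#' @param bounds Optional list with `lower` and `upper` (length 2, in the
#'   task's native coordinates). Defaults: epsilon within +/-50 %, sigma
#'   within +/-20 % of the initial value; xi and zeta in [-0.5, 0.5].
#' @param initial Optional initial point (native coordinates); defaults to the
#'   current parameter values.
#' @return An object of class `fit_task`.
#' @export
fit_task <- function(type, kind = c("self", "water-interaction"), subset,
                     subset_types = character(), water_type = NULL,
                     w_dG = 1, w_rho = 1, bounds = NULL, initial = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(subset), length(subset) >= 1)
  if (kind == "water-interaction" && is.null(water_type))
    stop("water-interaction tasks need a water_type")
  if (!is.null(bounds)) {
    stopifnot(is.list(bounds), length(bounds$lower) == 2, length(bounds$upper) == 2,
              all(is.finite(bounds$lower)), all(is.finite(bounds$upper)),
              all(bounds$lower < bounds$upper))
  }
  structure(list(type = type, kind = kind, subset = subset,
                 subset_types = subset_types, water_type = water_type,
                 w_dG = w_dG, w_rho = w_rho, bounds = bounds, initial = initial),
            class = "fit_task")
}

#' Assemble an adaptation schedule
#'
#' Validates the prerequisite structure: a task may only depend on atom types
#' that are fixed from the start or optimized by an earlier task — mirroring a
#' workflow where compounds enter the fit only once all their atom types have
#' been adapted, so compound complexity grows monotonically along the
#' schedule.
#'
#' @param tasks Ordered list of [fit_task()]s.
#' @param fixed_types Types considered fixed (never fitted, e.g. water oxygen
#'   and hydrogen types).
#' @return An object of class `adaptation_schedule`.
#' @export
adaptation_schedule <- function(tasks, fixed_types = character()) {
  if (inherits(tasks, "fit_task")) tasks <- list(tasks)
  stopifnot(all(vapply(tasks, inherits, logical(1), "fit_task")))
  done <- fixed_types
  for (i in seq_along(tasks)) {
    t <- tasks[[i]]
    need <- setdiff(t$subset_types, c(done, t$type))
    if (length(need))
      stop("task ", i, " (", t$type, ", ", t$kind, ") depends on atom types ",
           "not yet optimized or fixed: ", paste(need, collapse = ", "))
    done <- union(done, t$type)
  }
  structure(list(tasks = tasks, fixed_types = fixed_types),
            class = "adaptation_schedule")
}

#' The canonical adaptation order of the targeted atom types
#'
#' The 21 non-hydrogen atom types adapted by the refitting workflow, in the
#' order dictated by data volume and growing compound complexity: ring sp3
#' carbon first, then chain-end and aromatic carbons with the alcohol/phenol
#' oxygens, the chain sp3 carbon, ethers, chlorine, aromatic and amide
#' nitrogen chemistry, carbonyl and ester types, nitriles, bromine, amines,
#' and the halogens fluorine and iodine last.
#'
#' @return Character vector of 21 atom-type names.
#' @export
default_adaptation_order <- function() {
  c("c3R", "c3E", "ca", "oh", "ohP", "c3", "os", "cl", "nb", "c2", "c",
    "na", "o", "osE", "n", "n1", "c1", "br", "nh", "f", "i")
}

apply_task_params <- function(params, task, theta) {
  if (task$kind == "self")
    set_type_params(params, task$type, epsilon = theta[1], sigma = theta[2])
  else
    set_override(params, task$type, task$water_type, xi = theta[1], zeta = theta[2])
}

task_initial <- function(params, task) {
  if (!is.null(task$initial)) return(as.numeric(task$initial))
  if (task$kind == "self") {
    t <- get_type(params, task$type)
    c(t$epsilon, t$sigma)
  } else {
    o <- find_override(params, task$type, task$water_type)
    if (is.null(o)) c(0, 0) else c(o$xi, o$zeta)
  }
}

task_bounds <- function(task, theta0) {
  if (!is.null(task$bounds)) return(task$bounds)
  if (task$kind == "self")
    list(lower = c(0.5 * theta0[1], 0.8 * theta0[2]),
         upper = c(1.5 * theta0[1], 1.2 * theta0[2]))
  else
    list(lower = c(-0.5, -0.5), upper = c(0.5, 0.5))
}

#' Run the sequential atom-type adaptation
#'
#' Executes the schedule's tasks in order. For each task the evaluator is
#' first run at the current parameter set to obtain the reference RMSDs that
#' normalize the objective; the task's two coefficients are then optimized by
#' oriented multi-start Nelder-Mead, and the winning values are frozen into
#' the parameter set before the next task starts.
#'
#' Self tasks are optimized in coordinates scaled by their initial values so
#' epsilon and sigma are commensurate; water-interaction modifiers are already
#' dimensionless and are optimized natively.
#'
#' @param schedule An [adaptation_schedule()].
#' @param evaluator Function `(params, subset) -> list(rmsd_dG =, rmsd_rho =)`
#'   (either may be `NA` when the subset has no data of that property).
#' @param params0 Starting [parameter_set()].
#' @param n_restarts,max_iter,tol,diam_tol Optimizer controls per task.
#' @param on_error `"halt"` (default) or `"continue"`: what to do when the
#'   evaluator fails during a task; prior tasks' results are kept either way.
#' @return List with `params` (fitted set, label `"fitted"`) and `report`
#'   (one row per task: reference and final RMSDs, objective values, evaluation
#'   counts, convergence flags).
#' @export
sequential_fit <- function(schedule, evaluator, params0, n_restarts = 4,
                           max_iter = 200, tol = 1e-3, diam_tol = 1e-4,
                           on_error = c("halt", "continue")) {
  stopifnot(inherits(schedule, "adaptation_schedule"),
            inherits(params0, "ff_parameter_set"))
  on_error <- match.arg(on_error)
  params <- params0
  rows <- list()
  for (ti in seq_along(schedule$tasks)) {
    task <- schedule$tasks[[ti]]
    step <- function() {
      ref <- evaluator(params, task$subset)
      has_dG <- task$w_dG > 0 && is.finite(ref$rmsd_dG) && ref$rmsd_dG > 0
      has_rho <- task$w_rho > 0 && is.finite(ref$rmsd_rho) && ref$rmsd_rho > 0
      if (!has_dG && !has_rho)
        stop("task ", ti, " (", task$type, "): no usable reference RMSD")
      spec <- objective_spec(
        w_dG = if (has_dG) task$w_dG else 0,
        w_rho = if (has_rho) task$w_rho else 1e-12,
        rmsd_dG_ref = if (has_dG) ref$rmsd_dG else 1,
        rmsd_rho_ref = if (has_rho) ref$rmsd_rho else 1)
      if (!has_rho) spec$w_rho <- 0
      theta0 <- task_initial(params, task)
      b <- task_bounds(task, theta0)
      scaled <- task$kind == "self"
      sc <- if (scaled) abs(theta0) else c(1, 1)
      if (any(sc == 0)) sc[sc == 0] <- 1
      fobj <- function(x) {
        th <- x * sc
        p <- apply_task_params(params, task, th)
        ev <- evaluator(p, task$subset)
        objective_Z(if (has_dG) ev$rmsd_dG else 0,
                    if (has_rho) ev$rmsd_rho else 0, spec)
      }
      opt <- multi_start(fobj, theta0 / sc, n_restarts = n_restarts,
                         initial_scale = 0.1, tol = tol, diam_tol = diam_tol,
                         max_iter = max_iter,
                         lower = b$lower / sc, upper = b$upper / sc)
      theta <- opt$x_best * sc
      params <<- apply_task_params(params, task, theta)
      fin <- evaluator(params, task$subset)
      rows[[length(rows) + 1L]] <<- data.frame(
        task = ti, type = task$type, kind = task$kind,
        rmsd_dG_ref = ref$rmsd_dG %||% NA_real_, rmsd_rho_ref = ref$rmsd_rho %||% NA_real_,
        rmsd_dG = fin$rmsd_dG %||% NA_real_, rmsd_rho = fin$rmsd_rho %||% NA_real_,
        Z = opt$f_best, n_eval = opt$n_eval, converged = opt$converged,
        theta1 = theta[1], theta2 = theta[2])
    }
    res <- tryCatch(step(), error = function(e) e)
    if (inherits(res, "error")) {
      msg <- paste0("task ", ti, " (", task$type, ", ", task$kind,
                    ") failed: ", conditionMessage(res))
      if (on_error == "halt") stop(msg)
      warning(msg)
    }
  }
  params$label <- "fitted"
  list(params = params,
       report = if (length(rows)) do.call(rbind, rows) else NULL)
}
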