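# Derivative-free minimization: Nelder-Mead downhill simplex with box
# constraints by projection and oriented multi-start restarts. Written out
# explicitly (rather than wrapping optim) because the fitting loop needs
# deterministic traces, projection bounds and restart orientations.

project_box <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Nelder-Mead downhill simplex minimization
#'
#' Standard reflection/expansion/contraction/shrink iteration with
#' coefficients (1, 2, 0.5, 0.5). Robust to noisy objectives since only
#' function-value ranking is used, never derivatives. Bounds are enforced by
#' projecting trial points onto the box. The iteration stops when the spread
#' of function values over the simplex falls below
#' `tol * (1 + |f_best|)` and the simplex diameter below `diam_tol`, or at
#' `max_iter` evaluations (the result is then flagged unconverged, not an
#' error).
#'
#' @param f Objective function taking a numeric vector.
#' @param x0 Initial point (dimension >= 1).
#' @param initial_scale Relative size of the initial simplex offsets.
#' @param orientation Sign vector (+1/-1 per coordinate) orienting the initial
#'   simplex; recycled to the dimension.
#' @param tol Relative f-spread tolerance.
#' @param diam_tol Simplex diameter tolerance (same units as `x`).
#' @param max_iter Maximum function evaluations.
#' @param lower,upper Box bounds (default unbounded).
#' @return List with `x_best`, `f_best`, `n_eval`, `converged`, and `trace`
#'   (matrix of best-so-far f per iteration).
#' @export
nelder_mead <- function(f, x0, initial_scale = 0.1, orientation = 1,
                        tol = 1e-3, diam_tol = 1e-4, max_iter = 500,
                        lower = -Inf, upper = Inf) {
  n <- length(x0)
  stopifnot(n >= 1)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  if (any(lower >= upper)) stop("lower bounds must be below upper bounds")
  orientation <- rep_len(sign(orientation), n)
  orientation[orientation == 0] <- 1
  x0 <- project_box(x0, lower, upper)
  # initial simplex: x0 plus oriented offsets along each axis
  simplex <- matrix(rep(x0, n + 1), nrow = n + 1, byrow = TRUE)
  for (i in seq_len(n)) {
    off <- initial_scale * (if (x0[i] != 0) abs(x0[i]) else 1) * orientation[i]
    simplex[i + 1, i] <- simplex[i + 1, i] + off
    simplex[i + 1, ] <- project_box(simplex[i + 1, ], lower, upper)
    if (all(simplex[i + 1, ] == x0))  # projection collapsed the vertex
      simplex[i + 1, i] <- x0[i] - off
  }
  fv <- apply(simplex, 1, f)
  n_eval <- n + 1L
  trace <- numeric(0)
  alpha <- 1; gamma <- 2; rho <- 0.5; sigma_s <- 0.5
  converged <- FALSE
  repeat {
    ord <- order(fv)
    simplex <- simplex[ord, , drop = FALSE]; fv <- fv[ord]
    trace <- c(trace, fv[1])
    spread <- fv[n + 1] - fv[1]
    diam <- max(apply(simplex, 2, function(col) diff(range(col))))
    if (spread < tol * (1 + abs(fv[1])) && diam < diam_tol) {
      converged <- TRUE; break
    }
    if (n_eval >= max_iter) break
    centroid <- colMeans(simplex[seq_len(n), , drop = FALSE])
    xr <- project_box(centroid + alpha * (centroid - simplex[n + 1, ]), lower, upper)
    fr <- f(xr); n_eval <- n_eval + 1L
    if (fr < fv[1]) {
      xe <- project_box(centroid + gamma * (centroid - simplex[n + 1, ]), lower, upper)
      fe <- f(xe); n_eval <- n_eval + 1L
      if (fe < fr) { simplex[n + 1, ] <- xe; fv[n + 1] <- fe }
      else { simplex[n + 1, ] <- xr; fv[n + 1] <- fr }
    } else if (fr < fv[n]) {
      simplex[n + 1, ] <- xr; fv[n + 1] <- fr
    } else {
      xc <- project_box(centroid + rho * (simplex[n + 1, ] - centroid), lower, upper)
      fc <- f(xc); n_eval <- n_eval + 1L
      if (fc < fv[n + 1]) { simplex[n + 1, ] <- xc; fv[n + 1] <- fc }
      else {
        for (i in 2:(n + 1)) {
          simplex[i, ] <- project_box(
            simplex[1, ] + sigma_s * (simplex[i, ] - simplex[1, ]), lower, upper)
          fv[i] <- f(simplex[i, ]); n_eval <- n_eval + 1L
        }
      }
    }
  }
  ord <- order(fv)
  list(x_best = simplex[ord[1], ], f_best = fv[ord[1]], n_eval = n_eval,
       converged = converged, trace = trace)
}

#' Multi-start Nelder-Mead with oriented initial simplices
#'
#' Reruns [nelder_mead()] once per restart with a different orientation of the
#' initial simplex offsets (sign patterns over the coordinates, enumerated
#' deterministically), guarding against convergence to a local optimum, and
#' returns the best result.
#'
#' @inheritParams nelder_mead
#' @param n_restarts Number of restarts (>= 1).
#' @param orientations Optional list of orientation vectors; defaults to the
#'   first `n_restarts` sign patterns `(+,+,...), (-,+,...), (+,-,...), ...`.
#' @param ... Passed to [nelder_mead()].
#' @return As [nelder_mead()], plus `restart_f` (f_best of every restart).
#' @export
multi_start <- function(f, x0, n_restarts = 4, orientations = NULL, ...) {
  stopifnot(n_restarts >= 1)
  n <- length(x0)
  if (is.null(orientations)) {
    orientations <- lapply(seq_len(n_restarts) - 1L, function(code) {
      bits <- as.integer(intToBits(code))[seq_len(n)]
      ifelse(bits == 1L, -1, 1)
    })
  }
  results <- lapply(orientations[seq_len(min(n_restarts, length(orientations)))],
                    function(o) nelder_mead(f, x0, orientation = o, ...))
  fb <- vapply(results, `[[`, numeric(1), "f_best")
  best <- results[[which.min(fb)]]
  best$restart_f <- fb
  best
}
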