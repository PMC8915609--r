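# Multistate Bennett Acceptance Ratio estimator: self-consistent iteration
# with a Newton switch on the log-sum-exp formulation, asymptotic covariance,
# overlap diagnostics, and bootstrap uncertainties.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# vectorized column-wise log-sum-exp of a K x N matrix
col_logsumexp <- function(A) {
  m <- A[1, ]
  if (nrow(A) > 1) for (k in 2:nrow(A)) m <- pmax(m, A[k, ])
  m + log(colSums(exp(A - rep(m, each = nrow(A)))))
}

# W_nk = exp(f_k - u_kn) / sum_l N_l exp(f_l - u_ln); log-denominator per sample
mbar_log_denom <- function(u_kn, n_k, f) {
  col_logsumexp(log(n_k) + f - u_kn)
}

mbar_weights <- function(u_kn, n_k, f) {
  ld <- mbar_log_denom(u_kn, n_k, f)
  t(exp((f - u_kn) - rep(ld, each = nrow(u_kn))))   # N x K
}

#' Estimate free energies from a reduced-potential matrix with MBAR
#'
#' Solves the self-consistent MBAR equations for the dimensionless free
#' energies of K states (anchored at state 1 = 0), using damped self-consistent
#' iteration with an adaptive switch to Newton's method once the residual is
#' small. Uncertainties come from the asymptotic covariance matrix; the
#' state-overlap matrix is reported and a warning is raised when the smallest
#' consecutive-state overlap drops below 0.03.
#'
#' @param u_kn A [reduced_potential_matrix()], or a K x N numeric matrix of
#'   reduced potentials (beta * U).
#' @param n_k Samples per state (ignored when `u_kn` is a
#'   `reduced_potential_matrix`).
#' @param tol Convergence tolerance on the reduced free energies.
#' @param max_iter Maximum iterations; non-convergence is an error carrying
#'   the residual.
#' @param temperature If non-`NULL`, results are scaled by RT into kJ/mol;
#'   otherwise they stay dimensionless (RT = 1).
#' @return An object of class `free_energy_result`: `dG` (end-to-end, state 1
#'   to state K), `uncertainty`, `f_k` (per-state free energies),
#'   `per_interval` (data.frame of adjacent-state `dG` and `uncertainty`),
#'   `overlap` (K x K, rows sum to 1), `min_consecutive_overlap`, `iterations`.
#' @export
mbar_estimate <- function(u_kn, n_k = NULL, tol = 1e-10, max_iter = 10000,
                          temperature = NULL) {
  if (inherits(u_kn, "reduced_potential_matrix")) {
    n_k <- u_kn$n_k; u_kn <- u_kn$u_kn
  }
  stopifnot(is.matrix(u_kn), length(n_k) == nrow(u_kn), sum(n_k) == ncol(u_kn))
  if (nrow(u_kn) < 2) stop("MBAR needs at least 2 states")
  K <- nrow(u_kn)
  f <- numeric(K)
  # initialize by forward BAR-like exponential averaging
  for (k in 2:K) {
    idx <- sum(n_k[seq_len(k - 1)])
    span <- max(1, n_k[k - 1])
    cols <- (idx - span + 1):idx
    du <- u_kn[k, cols, drop = FALSE] - u_kn[k - 1, cols, drop = FALSE]
    f[k] <- f[k - 1] + (-logsumexp(-du) + log(length(cols)))
  }
  iter <- 0L; converged <- FALSE
  resid <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    ld <- mbar_log_denom(u_kn, n_k, f)
    f_new <- -vapply(seq_len(K), function(k) logsumexp(-u_kn[k, ] - ld),
                     numeric(1))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < max(tol, 1e-14)) { converged <- TRUE; break }
    if (resid < 1e-2 && K >= 2) {
      # Newton refinement on f[2..K]
      for (nit in 1:100) {
        W <- mbar_weights(u_kn, n_k, f)          # N x K
        g <- n_k * (colSums(W) - 1)
        # Hessian: H_kl = delta_kl N_k sum_n W_nk - N_k N_l sum_n W_nk W_nl
        WtW <- crossprod(W)
        H <- diag(n_k * colSums(W), K) - outer(n_k, n_k) * WtW
        idx <- 2:K
        step <- tryCatch(solve(H[idx, idx, drop = FALSE], g[idx]),
                         error = function(e) NULL)
        if (is.null(step)) break
        f[idx] <- f[idx] - step
        f <- f - f[1]
        if (max(abs(step)) < max(tol, 1e-14)) { converged <- TRUE; break }
      }
      if (converged) break
    }
  }
  if (!converged) {
    ld <- mbar_log_denom(u_kn, n_k, f)
    f_chk <- -vapply(seq_len(K), function(k) logsumexp(-u_kn[k, ] - ld),
                     numeric(1))
    f_chk <- f_chk - f_chk[1]
    resid <- max(abs(f_chk - f))
    if (resid >= max(tol * 100, 1e-9))
      stop("MBAR failed to converge within ", max_iter,
           " iterations (residual ", format(resid), ")")
  }
  W <- mbar_weights(u_kn, n_k, f)  # N x K, columns sum to 1 at the solution
  # asymptotic covariance (Shirts & Chodera, svd-based K x K reduction)
  WtW <- crossprod(W)
  eg <- eigen(WtW, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  V <- eg$vectors[, pos, drop = FALSE]
  S <- sqrt(eg$values[pos])
  Sv <- sweep(V, 2, S, `*`)                   # V %*% diag(S)
  inner <- diag(length(S)) - t(Sv) %*% (Sv * n_k)
  inner_p <- tryCatch(solve(inner), error = function(e) MASS_ginv(inner))
  Theta <- Sv %*% inner_p %*% t(Sv)
  dvar <- function(i, j) {
    v <- Theta[i, i] + Theta[j, j] - 2 * Theta[i, j]
    if (!is.finite(v) || v < 0) 0 else v
  }
  overlap <- sweep(WtW, 2, n_k, `*`)
  scale <- if (is.null(temperature)) 1 else GAS_CONSTANT * temperature
  per_int <- data.frame(
    from = seq_len(K - 1), to = 2:K,
    dG = scale * diff(f),
    uncertainty = scale * vapply(seq_len(K - 1), function(k)
      sqrt(dvar(k, k + 1)), numeric(1)))
  cons <- vapply(seq_len(K - 1), function(k) overlap[k, k + 1], numeric(1))
  min_overlap <- min(cons)
  if (min_overlap < 0.03)
    warning("minimum consecutive state overlap ", format(min_overlap, digits = 3),
            " < 0.03: configurational space overlap may be insufficient")
  structure(list(
    dG = scale * (f[K] - f[1]),
    uncertainty = scale * sqrt(dvar(1, K)),
    f_k = scale * f,
    per_interval = per_int,
    overlap = overlap,
    min_consecutive_overlap = min_overlap,
    iterations = iter, converged = TRUE, temperature = temperature),
    class = "free_energy_result")
}

# tiny Moore-Penrose fallback (avoids a MASS dependency)
MASS_ginv <- function(X, tol = 1e-12) {
  s <- svd(X)
  pos <- s$d > max(s$d) * tol
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.free_energy_result <- function(x, ...) {
  unit <- if (is.null(x$temperature)) "kT" else "kJ/mol"
  cat(sprintf("<free_energy_result> dG = %.4f +/- %.4f %s over %d states\n",
              x$dG, x$uncertainty, unit, length(x$f_k)))
  cat(sprintf("  min consecutive overlap %.3f, %d iterations\n",
              x$min_consecutive_overlap, x$iterations))
  invisible(x)
}

#' Bootstrap standard deviation of the MBAR free-energy difference
#'
#' Resamples configurations with replacement within each state's block,
#' re-estimates the end-to-end free-energy difference B times and returns the
#' standard deviation of the estimates.
#'
#' @param rpm A [reduced_potential_matrix()] (or K x N matrix with `n_k`).
#' @param n_k Samples per state when `rpm` is a bare matrix.
#' @param B Number of bootstrap replicates (>= 2).
#' @param seed RNG seed.
#' @param temperature As in [mbar_estimate()].
#' @return Standard deviation of the B estimates (kJ/mol, or kT when
#'   `temperature` is `NULL`).
#' @export
bootstrap_dG <- function(rpm, n_k = NULL, B = 50, seed = 1L, temperature = NULL) {
  if (inherits(rpm, "reduced_potential_matrix")) {
    n_k <- rpm$n_k; u_kn <- rpm$u_kn
  } else u_kn <- rpm
  if (B < 2) stop("B must be >= 2")
  set.seed(seed)
  offs <- c(0L, cumsum(n_k))
  ests <- vapply(seq_len(B), function(b) {
    cols <- unlist(lapply(seq_along(n_k), function(k)
      offs[k] + sample.int(n_k[k], n_k[k], replace = TRUE)))
    mbar_estimate(u_kn[, cols, drop = FALSE], n_k, tol = 1e-8,
                  temperature = temperature)$dG
  }, numeric(1))
  sd(ests)
}
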