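# Shared fixtures and independent oracles for the test suite. Everything is
# built in code; no binary fixtures.

# simple two-type parameter set used across forcefield/engine tests
tiny_params <- function() {
  parameter_set(list(atom_type("A", 0.6, 0.33, "generic"),
                     atom_type("S", 0.8, 0.34, "solvent")))
}

mono_molecule <- function(name, type, mass = 40)
  molecule_spec(name, site_spec(type), mass = mass)

pure_system <- function(type = "S", n = 20, box = 2.0, temperature = 80,
                        pressure = 1, mass = 40)
  system_spec(list(list(molecule = mono_molecule(paste0("m", type), type, mass),
                        count = n, role = "solvent")),
              box_edge = box, temperature = temperature, pressure = pressure)

# independent O(N^2) energy oracle in plain R: minimum image, spherical
# truncation, optional truncated-shifted Coulomb; no tail correction
brute_force_energy <- function(pos, box, r_cut, eps, sig, q = NULL,
                               mol = seq_len(nrow(pos))) {
  n <- nrow(pos)
  mi <- function(d) d - box * round(d / box)
  u <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (mol[i] == mol[j]) next
    r <- sqrt(sum(mi(pos[i, ] - pos[j, ])^2))
    if (r >= r_cut) next
    sr6 <- (sig / r)^6
    u <- u + 4 * eps * sr6 * (sr6 - 1)
    if (!is.null(q) && q[i] != 0 && q[j] != 0)
      u <- u + 138.935458 * q[i] * q[j] * (1 / r - 1 / r_cut)
  }
  u
}

# independent MBAR oracle: direct minimization of the MBAR negative
# log-likelihood with stats::optim (BFGS), anchored at f_1 = 0
mbar_oracle <- function(u_kn, n_k) {
  K <- nrow(u_kn)
  lse_col <- function(A) {
    m <- A[1, ]
    if (nrow(A) > 1) for (k in 2:nrow(A)) m <- pmax(m, A[k, ])
    m + log(colSums(exp(A - rep(m, each = nrow(A)))))
  }
  nll <- function(f_free) {
    f <- c(0, f_free)
    sum(lse_col(log(n_k) + f - u_kn)) - sum(n_k * f)
  }
  if (K == 2) {
    o <- optimize(function(x) nll(x), c(-50, 50), tol = 1e-14)
    c(0, o$minimum)
  } else {
    o <- optim(rep(0, K - 1), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
    c(0, o$par)
  }
}

# exact sampling of 1-D harmonic states u_k(x) = kappa_k x^2 / 2 (reduced
# units): returns the reduced potential matrix and n_k
harmonic_rpm <- function(kappas, n_per_state, seed = 1) {
  set.seed(seed)
  xs <- unlist(lapply(kappas, function(k) rnorm(n_per_state, 0, sqrt(1 / k))))
  u_kn <- do.call(rbind, lapply(kappas, function(k) k * xs^2 / 2))
  list(u_kn = u_kn, n_k = rep(n_per_state, length(kappas)),
       exact_df = 0.5 * log(kappas / kappas[1]))
}

random_charge_set <- function(n_sites, molecule = "mol", seed = 1) {
  set.seed(seed)
  q <- rnorm(n_sites)
  q <- q - mean(q)  # neutral
  charge_set(molecule, "vacuum", q)
}
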