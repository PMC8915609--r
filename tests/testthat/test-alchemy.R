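test_that("softcore endpoints and finiteness hold exactly", {
  grid <- expand.grid(eps = c(0.2, 0.8), sig = c(0.25, 0.4),
                      r = c(0.05, 0.2, 0.3, 0.5, 1.0))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_identical(softcore_lj(g$eps, g$sig, g$r, 1),
                     lj_energy(g$eps, g$sig, g$r))
    expect_identical(softcore_lj(g$eps, g$sig, g$r, 0), 0)
    expect_true(is.finite(softcore_lj(g$eps, g$sig, g$r, 0.5)))
  }
  expect_true(is.finite(softcore_lj(0.5, 0.3, 0, 0.5)))   # finite at r = 0
  expect_error(softcore_lj(0.5, 0.3, 0.3, 1.2), "lambda")
  expect_error(softcore_lj(0.5, 0.3, 0.3, -0.1), "lambda")
})

test_that("softcore is continuous in lambda on an r grid", {
  # at physically sampled distances (r >= ~0.9 sigma at the coupled end) the
  # profile is smooth on a fine grid
  lams <- seq(0, 1, by = 0.002)
  for (r in c(0.30, 0.33, 0.4, 0.5)) {
    u <- vapply(lams, function(l) softcore_lj(0.6, 0.33, r, l), numeric(1))
    expect_true(all(is.finite(u)))
    expect_lt(max(abs(diff(u)) / (1 + pmax(abs(u[-1]), abs(u[-length(u)])))),
              0.05)
  }
  # deep inside the core the 1-1-48 form is intrinsically steep as lambda -> 1
  # (it collapses onto the full r^-12 wall); continuity still holds away from
  # the coupled endpoint, and the endpoint value itself is the exact LJ energy
  for (r in c(0.05, 0.15)) {
    u <- vapply(seq(0, 0.9, by = 0.002), function(l)
      softcore_lj(0.6, 0.33, r, l), numeric(1))
    expect_true(all(is.finite(u)))
    expect_lt(max(abs(diff(u)) / (1 + pmax(abs(u[-1]), abs(u[-length(u)])))),
              0.05)
  }
})

test_that("R and C++ softcore implementations agree", {
  set.seed(31)
  for (rep in 1:30) {
    eps <- runif(1, 0.1, 1); sig <- runif(1, 0.25, 0.45)
    r <- runif(1, 0, 1); l <- runif(1)
    expect_equal(softcore_lj(eps, sig, r, l),
                 ljrefit:::cpp_softcore_lj(eps, sig, r, l, 0.003, 48L),
                 tolerance = 1e-12)
  }
})

test_that("lambda schedules are validated", {
  expect_error(lambda_schedule(c(0, 0.5)), "endpoints")
  expect_error(lambda_schedule(c(0, 0.5, 0.5, 1)), "increasing")
  expect_error(lambda_schedule(1), "at least 2")
  expect_equal(uniform_schedule(5)$values, seq(0, 1, 0.25))
})

test_that("redistribute_lambdas equalizes the cumulative uncertainty profile", {
  sched <- uniform_schedule(5)
  expect_equal(redistribute_lambdas(sched, rep(0.3, 4))$values, sched$values)
  # K = 3, uncertainties (3, 1): cumulative (0,3,4); midpoint target 2 ->
  # lambda = 0.5 * 2/3 = 1/3 (hand-derived piecewise-linear inversion)
  s3 <- redistribute_lambdas(lambda_schedule(c(0, 0.5, 1)), c(3, 1))
  expect_equal(s3$values, c(0, 1 / 3, 1))
  set.seed(12)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    unc <- runif(k - 1, 0.05, 2)
    new <- redistribute_lambdas(uniform_schedule(k), unc)
    expect_identical(new$values[1], 0)
    expect_identical(new$values[k], 1)
    expect_true(all(diff(new$values) > 0))
    expect_length(new$values, k)
  }
  expect_error(redistribute_lambdas(sched, c(0.3, -1, 0.3, 0.3)), "positive")
})

test_that("reduced potential matrices validate and round-trip", {
  u <- matrix(rnorm(12), 2, 6)
  expect_error(reduced_potential_matrix(u, c(3, 4)), "sum")
  expect_error(reduced_potential_matrix(u, c(6)), "length")
  rpm <- reduced_potential_matrix(u, c(3, 3), schedule = uniform_schedule(2),
                                  beta = 0.4)
  path <- withr::local_tempfile(fileext = ".dat")
  write_rpm(rpm, path)
  rpm2 <- read_rpm(path)
  expect_equal(rpm2$u_kn, rpm$u_kn, tolerance = 1e-12)
  expect_identical(rpm2$n_k, rpm$n_k)
  expect_equal(rpm2$beta, 0.4)
})

test_that("MBAR is exact for two identical states", {
  set.seed(3)
  u <- matrix(rep(rnorm(400), each = 2), 2, 400)
  est <- mbar_estimate(u, c(200, 200))
  expect_lt(abs(est$dG), 1e-8)
})

test_that("MBAR recovers the harmonic closed form within 3 SEM", {
  h <- harmonic_rpm(c(1, 4), 4000, seed = 17)
  est <- mbar_estimate(h$u_kn, h$n_k)
  expect_lt(abs(est$dG - h$exact_df[2]), 3 * est$uncertainty + 0.01)
  # with a temperature the result scales by RT
  estT <- mbar_estimate(h$u_kn, h$n_k, temperature = 300)
  expect_equal(estT$dG, est$dG * GAS_CONSTANT * 300)
})

test_that("MBAR matches the independent likelihood-optimization oracle", {
  set.seed(23)
  for (rep in 1:3) {
    K <- sample(2:4, 1)
    n_k <- sample(50:120, K, replace = TRUE)
    # random overlapping Gaussian states
    mus <- cumsum(runif(K, 0, 0.8))
    xs <- unlist(lapply(seq_len(K), function(k) rnorm(n_k[k], mus[k], 1)))
    u_kn <- do.call(rbind, lapply(seq_len(K), function(k) (xs - mus[k])^2 / 2))
    est <- mbar_estimate(u_kn, n_k)
    oracle <- mbar_oracle(u_kn, n_k)
    expect_lt(max(abs(est$f_k - oracle)), 1e-6)
  }
})

test_that("MBAR per-interval results telescope and overlap rows sum to 1", {
  h <- harmonic_rpm(c(1, 2, 4, 8), 500, seed = 5)
  est <- mbar_estimate(h$u_kn, h$n_k)
  expect_lt(abs(sum(est$per_interval$dG) - est$dG), 1e-8)
  expect_lt(max(abs(rowSums(est$overlap) - 1)), 1e-8)
  expect_true(all(est$per_interval$uncertainty >= 0))
})

test_that("MBAR warns on insufficient consecutive overlap", {
  set.seed(11)
  xs <- c(rnorm(200, 0, 0.1), rnorm(200, 30, 0.1))   # disjoint states
  u <- rbind((xs - 0)^2 / (2 * 0.01), (xs - 30)^2 / (2 * 0.01))
  u <- pmin(u, 700)  # keep finite
  expect_warning(mbar_estimate(u, c(200, 200), tol = 1e-6), "overlap")
})

test_that("bootstrap_dG is seeded and degenerates to zero", {
  u <- matrix(0, 2, 100)
  u[2, ] <- 1
  expect_equal(bootstrap_dG(reduced_potential_matrix(u, c(50, 50)), B = 10,
                            seed = 3), 0)
  h <- harmonic_rpm(c(1, 4), 300, seed = 2)
  rpm <- reduced_potential_matrix(h$u_kn, h$n_k)
  b1 <- bootstrap_dG(rpm, B = 20, seed = 9)
  b2 <- bootstrap_dG(rpm, B = 20, seed = 9)
  expect_identical(b1, b2)
  expect_error(bootstrap_dG(rpm, B = 1), "B must be")
  # estimator consistency: bootstrap SD within a factor 2 of asymptotic SD
  h2 <- harmonic_rpm(c(1, 4), 2000, seed = 21)
  est <- mbar_estimate(h2$u_kn, h2$n_k)
  bs <- bootstrap_dG(reduced_potential_matrix(h2$u_kn, h2$n_k), B = 40, seed = 4)
  expect_gt(bs, est$uncertainty / 2)
  expect_lt(bs, est$uncertainty * 2)
})

test_that("sample_alchemical fulfills its shape/determinism/cross-check contracts", {
  ps <- tiny_params()
  sol <- mono_molecule("probe", "A", 30)
  n <- 12; box <- 1.6
  sys <- system_spec(list(list(molecule = mono_molecule("mS", "S"), count = n,
                               role = "solvent"),
                          list(molecule = sol, count = 1, role = "solute")),
                     box_edge = box, temperature = 80)
  st <- sim_settings(temperature = 80, n_steps = 300, equil_steps = 100,
                     sample_interval = 10, r_cut = 0.75,
                     tail_correction = FALSE, seed = 13)
  sched <- uniform_schedule(4)
  rpm <- sample_alchemical(sys, ps, sched, st)
  expect_identical(dim(rpm$u_kn), c(4L, as.integer(sum(rpm$n_k))))
  expect_identical(rpm$n_k, rep(20L, 4))
  rpm2 <- sample_alchemical(sys, ps, sched, st)
  expect_identical(rpm$u_kn, rpm2$u_kn)
  expect_error(sample_alchemical(pure_system("S", 5, 1.6, 80), ps, sched, st),
               "no solute")
})

test_that("coupled-state reduced potentials equal a total_energy difference", {
  # at lambda = 1 the solute-solvent term is plain LJ, so the recorded reduced
  # potential must equal beta * (E(full system) - E(solvent alone)) with tail
  # correction off
  ps <- tiny_params()
  n <- 10; box <- 1.6; temp <- 80
  solv <- mono_molecule("mS", "S")
  sys <- system_spec(list(list(molecule = solv, count = n, role = "solvent"),
                          list(molecule = mono_molecule("probe", "A", 30),
                               count = 1, role = "solute")),
                     box_edge = box, temperature = temp)
  st <- sim_settings(temperature = temp, n_steps = 200, equil_steps = 100,
                     sample_interval = 20, r_cut = 0.75,
                     tail_correction = FALSE, seed = 19)
  sched <- lambda_schedule(c(0, 1))
  ex <- ljrefit:::expand_system(sys, ps)
  st2 <- st; st2$seed <- st$seed + 2000L
  res <- ljrefit:::run_mc_engine(sys, ps, st2, npt = FALSE, store_configs = TRUE,
                                 smol = ex$solute_mol, lambda = 1)
  rpm <- sample_alchemical(sys, ps, sched, st)
  beta <- 1 / (GAS_CONSTANT * temp)
  # recompute the coupled-state row for the coupled trajectory's samples
  k_cols <- (rpm$n_k[1] + 1):sum(rpm$n_k)
  solv_sys <- system_spec(list(list(molecule = solv, count = n, role = "solvent")),
                          box_edge = box, temperature = temp)
  for (i in seq_along(k_cols)) {
    pos <- matrix(res$configs[i, ], ncol = 3, byrow = TRUE)
    e_full <- total_energy(configuration(pos, box), sys, ps, st)
    e_solv <- total_energy(configuration(pos[seq_len(n), , drop = FALSE], box),
                           solv_sys, ps, st)
    expect_equal(rpm$u_kn[2, k_cols[i]], beta * (e_full - e_solv),
                 tolerance = 1e-8)
  }
})

test_that("solvation_free_energy handles trivial and sign-oracle cases", {
  # non-interacting solute: dG = 0 up to noise
  ps0 <- parameter_set(list(atom_type("A", 0, 0.33), atom_type("S", 0.6, 0.34)))
  n <- 15; box <- 1.7
  sys <- system_spec(list(list(molecule = mono_molecule("mS", "S"), count = n,
                               role = "solvent"),
                          list(molecule = mono_molecule("probe", "A", 30),
                               count = 1, role = "solute")),
                     box_edge = box, temperature = 80)
  st <- sim_settings(temperature = 80, n_steps = 500, equil_steps = 200,
                     sample_interval = 5, r_cut = 0.8, seed = 3)
  fe0 <- solvation_free_energy(sys, ps0, uniform_schedule(3), st,
                               n_trial_rounds = 0)
  expect_lt(abs(fe0$dG), 3 * fe0$uncertainty + 1e-8)
  # oversized nearly-hard solute in a dense solvent: cavity work dominates
  psr <- parameter_set(list(atom_type("A", 0.05, 0.55), atom_type("S", 0.6, 0.34)))
  nd <- 40; boxd <- (nd * 0.34^3 / 0.7)^(1 / 3)
  sysd <- system_spec(list(list(molecule = mono_molecule("mS", "S"), count = nd,
                                role = "solvent"),
                           list(molecule = mono_molecule("probe", "A", 30),
                                count = 1, role = "solute")),
                      box_edge = boxd, temperature = 70)
  str <- sim_settings(temperature = 70, n_steps = 1500, equil_steps = 500,
                      sample_interval = 5, r_cut = 0.49 * boxd, seed = 5)
  # a nearly-hard solute has weak decoupled/coupled overlap by construction;
  # the overlap warning is expected here
  fer <- suppressWarnings(
    solvation_free_energy(sysd, psr, uniform_schedule(5), str,
                          n_trial_rounds = 1))
  expect_gt(fer$dG, 0)
})
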