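test_that("total_energy matches an independent brute-force oracle", {
  set.seed(5)
  ps <- tiny_params()
  sys <- pure_system("A", n = 5, box = 2.0)
  st <- sim_settings(r_cut = 0.9, tail_correction = FALSE,
                     n_steps = 10, equil_steps = 0)
  for (rep in 1:5) {
    pos <- matrix(runif(15, 0, 2), 5, 3)
    e <- total_energy(configuration(pos, 2.0), sys, ps, st)
    bf <- brute_force_energy(pos, 2.0, 0.9, 0.6, 0.33)
    expect_equal(e, bf, tolerance = 1e-10)
  }
})

test_that("total_energy honors trivial zero cases and geometry errors", {
  ps <- tiny_params()
  sys <- pure_system("A", n = 2, box = 3.0)
  st <- sim_settings(r_cut = 1.2, tail_correction = FALSE, n_steps = 10,
                     equil_steps = 0)
  pos <- rbind(c(0.5, 0.5, 0.5), c(0.5 + 0.33, 0.5, 0.5))  # r = sigma
  expect_equal(total_energy(configuration(pos, 3.0), sys, ps, st), 0,
               tolerance = 1e-12)
  ps0 <- parameter_set(list(atom_type("A", 0, 0.33), atom_type("S", 0, 0.34)))
  posr <- matrix(runif(6, 0, 3), 2, 3)
  expect_equal(total_energy(configuration(posr, 3.0), sys, ps0, st), 0)
  expect_error(total_energy(configuration(pos, 1.5), sys, ps, st), "minimum image")
})

test_that("charged pairs add truncated-shifted Coulomb", {
  ps <- tiny_params()
  m <- molecule_spec("ion", site_spec("A", charge = 0.5), mass = 30)
  sys <- system_spec(list(list(molecule = m, count = 4, role = "solvent")),
                     box_edge = 3.0, temperature = 100)
  st <- sim_settings(r_cut = 1.2, tail_correction = FALSE, n_steps = 10,
                     equil_steps = 0)
  set.seed(8)
  pos <- matrix(runif(12, 0, 3), 4, 3)
  e <- total_energy(configuration(pos, 3.0), sys, ps, st)
  bf <- brute_force_energy(pos, 3.0, 1.2, 0.6, 0.33, q = rep(0.5, 4))
  expect_equal(e, bf, tolerance = 1e-10)
})

test_that("run_nvt is deterministic and accepts everything for an ideal gas", {
  ps0 <- parameter_set(list(atom_type("A", 0, 0.33), atom_type("S", 0, 0.34)))
  sys <- pure_system("A", n = 10, box = 2.0, temperature = 300)
  st <- sim_settings(temperature = 300, n_steps = 300, equil_steps = 100,
                     sample_interval = 2, r_cut = 0.9, seed = 42)
  r1 <- run_nvt(sys, ps0, st)
  expect_equal(r1$acc_displacement, 1.0)      # dU = 0 always
  r2 <- run_nvt(sys, ps0, st)
  expect_identical(r1$energy, r2$energy)      # bit-identical trajectory
})

test_that("2-particle NVT mean energy matches the quadrature oracle", {
  eps <- 0.5; sig <- 0.33; box <- 1.6; rc <- 0.79; temp <- 60
  ps <- parameter_set(list(atom_type("A", eps, sig), atom_type("S", 0.8, 0.34)))
  sys <- pure_system("A", n = 2, box = box, temperature = temp)
  st <- sim_settings(temperature = temp, n_steps = 60000, equil_steps = 5000,
                     sample_interval = 5, r_cut = rc, tail_correction = FALSE,
                     max_displacement = 0.3, seed = 4)
  out <- run_nvt(sys, ps, st)
  beta <- 1 / (GAS_CONSTANT * temp)
  u <- function(r) 4 * eps * ((sig / r)^12 - (sig / r)^6)
  # pair displacement is uniform over the box; u = 0 beyond the cutoff, so
  # <U> = int_0^rc u e^(-bu) 4 pi r^2 dr / (V + int_0^rc (e^(-bu)-1) 4 pi r^2 dr)
  num <- integrate(function(r) u(r) * exp(-beta * u(r)) * 4 * pi * r^2,
                   0.1, rc, rel.tol = 1e-10)$value
  den <- box^3 + integrate(function(r) (exp(-beta * u(r)) - 1) * 4 * pi * r^2,
                           1e-3, rc, rel.tol = 1e-10)$value
  expected <- num / den
  sem <- block_sem(out$energy, 5)
  expect_lt(abs(mean(out$energy) - expected), 3 * sem + 0.002)
})

test_that("incremental energy bookkeeping stays on top of recomputation", {
  ps <- tiny_params()
  sys <- pure_system("A", n = 30, box = 1.8, temperature = 70)
  st <- sim_settings(temperature = 70, n_steps = 400, equil_steps = 0,
                     sample_interval = 10, r_cut = 0.89, seed = 2,
                     max_displacement = 0.1)
  out <- run_nvt(sys, ps, st)  # 400 sweeps x 30 molecules = 12000 moves
  expect_lt(abs(out$final_pair_energy - out$recomputed_pair_energy), 1e-6)
})

test_that("NPT ideal-gas density matches p/(RT) and the block-SEM formula", {
  psi <- parameter_set(list(atom_type("I", 0, 0.3)))
  mi <- molecule_spec("mI", site_spec("I"), mass = 40)
  sys <- system_spec(list(list(molecule = mi, count = 100, role = "solvent")),
                     box_edge = 10, temperature = 300, pressure = 1)
  st <- sim_settings(temperature = 300, pressure = 1, n_steps = 3000,
                     equil_steps = 1000, r_cut = 1.2, volume_move_scale = 0.15,
                     sample_interval = 2, seed = 7)
  out <- run_npt_density(sys, psi, st)
  molar <- out$density / 0.040                 # mol/m^3 (mass 40 g/mol)
  ideal <- 1e5 / (8.314462618 * 300)
  expect_lt(abs(molar - ideal), 3 * out$sem / 0.040 + 0.01 * ideal)
  # determinism
  out2 <- run_npt_density(sys, psi, st)
  expect_identical(c(out$density, out$sem), c(out2$density, out2$sem))
  # SEM equals the direct block-mean formula on the recorded series
  x <- out$stats$density
  per <- length(x) %/% 5
  bm <- vapply(1:5, function(b) mean(x[((b - 1) * per + 1):(b * per)]), numeric(1))
  expect_equal(out$sem, sd(bm) / sqrt(5))
})

test_that("Widom insertion into an ideal gas gives zero", {
  ps0 <- parameter_set(list(atom_type("A", 0, 0.33), atom_type("S", 0, 0.34)))
  sys <- pure_system("A", n = 15, box = 2.0, temperature = 300)
  st <- sim_settings(temperature = 300, n_steps = 400, equil_steps = 100,
                     sample_interval = 5, r_cut = 0.9, seed = 6)
  traj <- run_nvt(sys, ps0, st, store_configs = TRUE)
  w <- widom_mu_excess(traj, mono_molecule("probe", "S", 30), sys, ps0, st,
                       n_insertions = 50)
  expect_equal(w$mu_ex, 0)
  # fixed seed reproducibility
  w2 <- widom_mu_excess(traj, mono_molecule("probe", "S", 30), sys, ps0, st,
                        n_insertions = 50)
  expect_identical(w$mu_ex, w2$mu_ex)
  expect_error(widom_mu_excess(run_nvt(sys, ps0, st), mono_molecule("p", "S"),
                               sys, ps0, st), "store_configs")
})

test_that("dilute-fluid Widom mu_ex matches the virial-expansion oracle", {
  eps <- 0.5; sig <- 0.33; temp <- 120
  ps <- parameter_set(list(atom_type("A", eps, sig), atom_type("S", eps, sig)))
  n <- 30; rho_star <- 0.05
  box <- (n * sig^3 / rho_star)^(1 / 3)
  sys <- pure_system("A", n = n, box = box, temperature = temp)
  st <- sim_settings(temperature = temp, n_steps = 4000, equil_steps = 1000,
                     sample_interval = 4, r_cut = min(1.2, 0.49 * box),
                     tail_correction = FALSE, max_displacement = 0.4, seed = 9)
  traj <- run_nvt(sys, ps, st, store_configs = TRUE)
  w <- widom_mu_excess(traj, mono_molecule("probe", "A", 40), sys, ps, st,
                       n_insertions = 400)
  beta <- 1 / (GAS_CONSTANT * temp)
  rc <- min(1.2, 0.49 * box)
  u <- function(r) 4 * eps * ((sig / r)^12 - (sig / r)^6)
  b2 <- -0.5 * integrate(function(r) (exp(-beta * u(r)) - 1) * 4 * pi * r^2,
                         1e-3, rc, rel.tol = 1e-10)$value
  expected <- 2 * (n / box^3) * b2 / beta   # mu_ex ~ 2 rho B2 RT
  expect_lt(abs(w$mu_ex - expected), 3 * w$sem + 0.25 * abs(expected))
})
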