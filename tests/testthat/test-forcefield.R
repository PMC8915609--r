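test_that("lj_energy matches its closed form", {
  expect_equal(lj_energy(0.5, 0.3, 0.3), 0)                       # u(sigma) = 0
  expect_equal(lj_energy(0.5, 0.3, 2^(1 / 6) * 0.3), -0.5)        # minimum = -eps
  # (sigma/r) = 0.5: 4*0.65*(0.5^12 - 0.5^6) = -0.0399932861...
  expect_equal(lj_energy(0.65, 0.31, 0.62), 4 * 0.65 * (0.5^12 - 0.5^6),
               tolerance = 1e-12)
  expect_equal(round(lj_energy(0.65, 0.31, 0.62), 4), -0.04)
  expect_error(lj_energy(0.5, 0.3, 0), "positive")
  expect_error(lj_energy(0.5, -0.3, 0.5), "positive")
  expect_error(lj_energy(-0.5, 0.3, 0.5), "non-negative")
})

test_that("lj_energy is negative beyond sigma and vanishes at range", {
  r <- seq(0.301, 2, by = 0.001)
  u <- lj_energy(0.5, 0.3, r)
  expect_true(all(u < 0))
  expect_lt(abs(lj_energy(0.5, 0.3, 50)), 1e-12)
  expect_true(all(lj_energy(0.5, 0.3, seq(0.1, 0.29, by = 0.01)) > 0))
})

test_that("combine_pair implements (modified) Lorentz-Berthelot", {
  a <- atom_type("a", 0.4, 0.3)
  expect_equal(combine_pair(a, a), c(epsilon = 0.4, sigma = 0.3))
  i <- atom_type("i", 0.1, 0.2); j <- atom_type("j", 0.9, 0.4)
  expect_equal(combine_pair(i, j, interaction_override("i", "j", 0, 0)),
               c(epsilon = 0.3, sigma = 0.3))
  o <- interaction_override("a", "a", xi = 0.1, zeta = -0.05)
  expect_equal(combine_pair(a, a, o), c(epsilon = 0.44, sigma = 0.285))
})

test_that("combine_pair is symmetric and zero-override is exact identity", {
  set.seed(99)
  for (rep in 1:20) {
    i <- atom_type("i", runif(1, 0.1, 1.5), runif(1, 0.2, 0.5))
    j <- atom_type("j", runif(1, 0.1, 1.5), runif(1, 0.2, 0.5))
    o <- interaction_override("i", "j", runif(1, -0.4, 0.4), runif(1, -0.4, 0.4))
    expect_identical(combine_pair(i, j, o), combine_pair(j, i, o))
    o0 <- interaction_override("i", "j", 0, 0)
    expect_identical(combine_pair(i, j, o0), combine_pair(i, j))
  }
})

test_that("parameter_set enforces its invariants", {
  expect_error(parameter_set(list(atom_type("a", 0.1, 0.3),
                                  atom_type("a", 0.2, 0.3))), "duplicate")
  expect_error(parameter_set(list(atom_type("a", 0.1, 0.3)),
                             list(interaction_override("a", "zz", 0.1, 0))),
               "undefined")
  expect_error(parameter_set(list(atom_type("hw", 0.1, 0.2))), "epsilon = 0")
  # water hydrogens with zero epsilon pass
  ps <- parameter_set(list(atom_type("wO", 0.65, 0.315),
                           atom_type("hw", 0, 0.1)))
  expect_s3_class(ps, "ff_parameter_set")
  expect_error(atom_type("a", -0.1, 0.3), "non-negative")
  expect_error(atom_type("a", 0.1, 0), "positive")
})

test_that("aliases resolve to canonical types", {
  ps <- parameter_set(list(atom_type("ca", 0.36, 0.34)),
                      aliases = c(cc = "ca", cd = "ca"))
  expect_identical(resolve_type(ps, "cd"), "ca")
  expect_identical(get_type(ps, "cc")$epsilon, 0.36)
  expect_error(resolve_type(ps, "zz"), "unknown")
  expect_error(parameter_set(list(atom_type("ca", 0.36, 0.34)),
                             aliases = c(cc = "nope")), "undefined")
})

test_that("parameter files round-trip at documented precision", {
  ps <- parameter_set(
    list(atom_type("c3R", 0.457812, 0.339967, "ring sp3 carbon"),
         atom_type("wO", 0.636386, 0.315061, "water oxygen"),
         atom_type("hw", 0, 0.1, "water hydrogen")),
    list(interaction_override("c3R", "wO", 0.0317, -0.0123)),
    label = "fit-step-7", aliases = c(c3x = "c3R"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_parameter_file(ps, path)
  ps2 <- read_parameter_file(path)
  expect_equal(ps2$label, "fit-step-7")
  expect_equal(names(ps2$types), names(ps$types))
  for (nm in names(ps$types)) {
    expect_equal(ps2$types[[nm]]$epsilon, ps$types[[nm]]$epsilon, tolerance = 1e-6)
    expect_equal(ps2$types[[nm]]$sigma, ps$types[[nm]]$sigma, tolerance = 1e-6)
  }
  expect_equal(ps2$overrides[[1]]$xi, 0.0317)
  expect_equal(ps2$aliases[["c3x"]], "c3R")
})

test_that("malformed parameter files are rejected", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("[types]", "a 0.5 0.3", "[overrides]", "a zz 0.1 0.0"), path)
  expect_error(read_parameter_file(path), "undefined")
  writeLines(c("[types]", "a 0.5 0.3", "a 0.6 0.3"), path)
  expect_error(read_parameter_file(path), "duplicate")
})

test_that("GROMACS-style nonbonded export writes all combined pairs", {
  ps <- tiny_params()
  path <- withr::local_tempfile(fileext = ".itp")
  export_gromacs_nonbond(ps, path)
  lines <- readLines(path)
  expect_true(any(grepl("nonbond_params", lines)))
  # 2 types -> 3 unordered pairs
  expect_length(grep("^[A-Za-z]", lines[-(1:2)]), 3)
})

test_that("set_type_params and set_override keep the set valid", {
  ps <- tiny_params()
  ps <- set_type_params(ps, "A", epsilon = 0.7)
  expect_equal(get_type(ps, "A")$epsilon, 0.7)
  expect_equal(get_type(ps, "A")$sigma, 0.33)
  ps <- set_override(ps, "A", "S", 0.1, 0.02)
  ps <- set_override(ps, "S", "A", 0.2, 0.03)  # replaces, symmetric key
  expect_length(ps$overrides, 1)
  expect_equal(ps$overrides[[1]]$xi, 0.2)
})
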