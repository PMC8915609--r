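test_that("error_stats computes RMSD and MAE", {
  expect_equal(error_stats(c(1, 2, 3), c(1, 2, 3)), c(rmsd = 0, mae = 0))
  expect_equal(error_stats(2, 0), c(rmsd = 2, mae = 2))
  expect_equal(error_stats(c(0, 0), c(1, -1)), c(rmsd = 1, mae = 1))
  expect_error(error_stats(numeric(), numeric()), "empty")
  expect_error(error_stats(1:3, 1:2), "length")
})

test_that("RMSD >= MAE on random data", {
  set.seed(77)
  for (rep in 1:20) {
    s <- rnorm(50); e <- rnorm(50)
    es <- error_stats(s, e)
    expect_gte(es[["rmsd"]], es[["mae"]])
  }
})

test_that("regression_stats: through-origin slope and Pearson R", {
  x <- c(1, 2, 3, 4)
  expect_equal(regression_stats(x, x), c(slope = 1, pearson = 1))
  expect_equal(regression_stats(2 * x, x), c(slope = 2, pearson = 1))
  set.seed(42)
  s <- rnorm(30); e <- rnorm(30)
  rs <- regression_stats(s, e)
  expect_equal(rs[["slope"]], sum(e * s) / sum(e^2))       # textbook formula
  expect_equal(rs[["pearson"]],
               sum((s - mean(s)) * (e - mean(e))) /
                 sqrt(sum((s - mean(s))^2) * sum((e - mean(e))^2)))
  expect_error(regression_stats(1, 1), "at least 2")
  expect_error(regression_stats(c(1, 2), c(3, 3)), "zero variance")
})

make_eval_dataset <- function() {
  set.seed(8)
  n <- 24
  reference_dataset(data.frame(
    id = paste0("s", 1:n), property = "dGsolv",
    experimental = rnorm(n), simulated = rnorm(n),
    solute_group = rep(c("alcohols", "ethers", "arenes"), each = 8),
    solvent_group = rep(c("water", "alkanes"), times = 12),
    temperature = rep(c(280, 300, 320), times = 8)))
}

test_that("grouped_rmsd matches subset-wise recomputation", {
  ds <- make_eval_dataset()
  tab <- grouped_rmsd(ds, "solute_group")
  for (g in c("alcohols", "ethers", "arenes")) {
    sub <- ds[ds$solute_group == g, ]
    expect_equal(tab$rmsd[tab$group == g],
                 unname(error_stats(sub$simulated, sub$experimental)["rmsd"]))
  }
  # single group: group RMSD equals overall
  one <- ds; one$solute_group <- "only"
  t1 <- grouped_rmsd(one, "solute_group")
  expect_equal(t1$rmsd[t1$group == "only"], attr(t1, "overall"))
  # overall invariant to the grouping key
  expect_equal(attr(grouped_rmsd(ds, "solute_group"), "overall"),
               attr(grouped_rmsd(ds, "solvent_group"), "overall"))
})

test_that("temperature bins are lower-exclusive / upper-inclusive", {
  ds <- reference_dataset(data.frame(
    id = c("a", "b", "c"), property = "density",
    experimental = c(1, 2, 3), simulated = c(1, 2, 3),
    temperature = c(263.15, 293.15, 293.16)))
  tab <- grouped_rmsd(ds, "temperature", temperature_breaks = c(263.15, 293.15))
  # boundary values 263.15 and 293.15 fall in the lower-closed bins
  expect_equal(tab$n[tab$group == "(-Inf,263]"], 1)
  expect_equal(tab$n[grepl("263.*293", tab$group)], 1)
  expect_equal(tab$n[grepl("293.*Inf", tab$group)], 1)
})

test_that("objective_Z is the weighted sum of RMSD ratios", {
  spec <- objective_spec(1, 1, rmsd_dG_ref = 2, rmsd_rho_ref = 10)
  expect_equal(objective_Z(2, 10, spec), 2)         # unaltered baseline
  expect_equal(objective_Z(1, 5, spec), 1)          # both halved
  spec2 <- objective_spec(0.7, 0.3, rmsd_dG_ref = 1, rmsd_rho_ref = 1)
  expect_equal(objective_Z(2, 1, spec2), 1.7)
  expect_error(objective_spec(0, 0, 1, 1), "both")
  expect_error(objective_spec(1, 1, 0, 1), "positive")
  # linear in each weight, strictly increasing in each RMSD
  set.seed(1)
  for (rep in 1:10) {
    w <- runif(2, 0.1, 2); refs <- runif(2, 0.5, 5); r <- runif(2, 0.1, 4)
    sp <- objective_spec(w[1], w[2], refs[1], refs[2])
    sp2 <- objective_spec(2 * w[1], w[2], refs[1], refs[2])
    expect_equal(objective_Z(r[1], r[2], sp2) - objective_Z(r[1], r[2], sp),
                 w[1] * r[1] / refs[1])
    expect_gt(objective_Z(r[1] + 0.1, r[2], sp), objective_Z(r[1], r[2], sp))
    expect_gt(objective_Z(r[1], r[2] + 0.1, sp), objective_Z(r[1], r[2], sp))
  }
})

test_that("percent_reduction reproduces the benchmark improvements", {
  stats <- published_summary_stats()
  resp_full <- published_stat(stats, "validation2_relsol", "GAFF/RESP", "rmsd")
  fit_full <- published_stat(stats, "validation2_relsol",
                             "GAFF/IPolQ-Mod+LJ-Fit", "rmsd")
  expect_equal(round(percent_reduction(resp_full, fit_full), 1), 62.9)
  resp_sub <- published_stat(stats, "validation2_relsol", "GAFF/RESP", "rmsd",
                             "subset")
  fit_sub <- published_stat(stats, "validation2_relsol",
                            "GAFF/IPolQ-Mod+LJ-Fit", "rmsd", "subset")
  expect_equal(round(percent_reduction(resp_sub, fit_sub), 1), 24.2)
  expect_equal(percent_reduction(3, 3), 0)
  expect_error(percent_reduction(0, 1), "positive")
})

test_that("evaluation_report aggregates all statistics with exclusions", {
  ds <- make_eval_dataset()
  rep_ <- evaluation_report(ds, temperature_breaks = c(290),
                            exclude_groups = "arenes")
  expect_equal(rep_$rmsd,
               unname(error_stats(ds$simulated, ds$experimental)["rmsd"]))
  expect_true(rep_$rmsd >= rep_$mae)
  expect_lte(abs(rep_$pearson), 1)
  expect_equal(rep_$excluding$n, 16)
  keep <- ds$solute_group != "arenes"
  expect_equal(rep_$excluding$rmsd,
               unname(error_stats(ds$simulated[keep], ds$experimental[keep])["rmsd"]))
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep_, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$n, 24)
})

test_that("reference datasets validate and round-trip as CSV", {
  expect_error(reference_dataset(data.frame(id = 1)), "missing columns")
  expect_error(reference_dataset(data.frame(id = c("a", "a"),
                                            property = "dGsolv",
                                            experimental = 1:2)), "unique")
  expect_error(reference_dataset(data.frame(id = "a", property = "foo",
                                            experimental = 1)), "property")
  ds <- make_eval_dataset()
  path <- withr::local_tempfile(fileext = ".csv")
  write_reference_csv(ds, path)
  ds2 <- read_reference_csv(path)
  expect_equal(ds2$experimental, ds$experimental)
  expect_equal(ds2$solute_group, ds$solute_group)
})
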