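# Differential evolution, structure fitting, packaged ranges.

test_that("evaluation bookkeeping is exact", {
  expect_identical(total_evaluations(20, 50), 1020L)
  expect_identical(total_evaluations(30, 50), 1530L)
  expect_identical(total_evaluations(50, 50), 2550L)
  expect_identical(total_evaluations(40, 100), 4040L)
})

test_that("config and spec validation reject bad settings", {
  expect_error(optimizer_config(population = 3), "population")
  expect_error(optimizer_config(generations = 0), "generations")
  expect_error(optimizer_config(F = 2.5), "F")
  expect_error(optimizer_config(CR = 1.2), "CR")
  expect_error(parameter_spec("x", 2, 1), "lower bound")
})

sphere_specs <- list(parameter_spec("x", -5, 5), parameter_spec("y", -5, 5),
                     parameter_spec("z", -5, 5))
sphere <- function(p) sum(p^2)

test_that("DE minimizes the sphere function at the paper budget", {
  for (seed in c(1, 7)) {
    fit <- run_de(sphere, sphere_specs, optimizer_config(20, 50, seed))
    expect_lt(fit$best_score, 1e-2)
    expect_identical(fit$n_evaluations, 1020L)
    expect_identical(names(fit$best_params), c("x", "y", "z"))
  }
})

test_that("runs are deterministic per seed and history is non-increasing", {
  f1 <- run_de(sphere, sphere_specs, optimizer_config(10, 20, seed = 4))
  f2 <- run_de(sphere, sphere_specs, optimizer_config(10, 20, seed = 4))
  expect_identical(f1$best_params, f2$best_params)
  expect_identical(f1$history, f2$history)
  expect_equal(length(f1$history), 21)
  expect_true(all(diff(f1$history) <= 0))
  f3 <- run_de(sphere, sphere_specs, optimizer_config(10, 20, seed = 5))
  expect_false(identical(f1$history, f3$history))
})

test_that("the optimizer does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(3)
  set.seed(99)
  invisible(run_de(sphere, sphere_specs, optimizer_config(8, 5, seed = 2)))
  expect_identical(runif(3), before)
})

test_that("mostly non-finite parent objectives abort with advice", {
  bad <- function(p) NaN
  expect_error(run_de(bad, sphere_specs, optimizer_config(8, 5)),
               "parameter ranges")
})

test_that("integer-kind parameters are rounded at evaluation time", {
  seen <- new.env(); seen$vals <- numeric(0)
  f <- function(p) {
    seen$vals <- c(seen$vals, p[["k"]])
    (p[["k"]] - 3)^2 + p[["x"]]^2
  }
  fit <- run_de(f, list(parameter_spec("k", 0, 10, kind = "integer"),
                        parameter_spec("x", -1, 1)),
                optimizer_config(10, 15, seed = 2))
  expect_true(all(seen$vals == round(seen$vals)))
  expect_identical(unname(fit$best_params[["k"]]), 3)
})

test_that("fit_structure recovers a noiseless dimer and checks compatibility", {
  target <- build_coiled_coil(crick_params(2, superhelix_radius = 4.5,
                                           pitch = 120, interface_angle = 5,
                                           n_residues = 16))
  fit <- fit_structure(target, "coiled_coil", ranges = "dimer",
                       cfg = optimizer_config(20, 50, seed = 1))
  expect_lt(fit$best_rmsd, 0.25)
  expect_s3_class(fit$best_model, "Assembly")
  expect_equal(fit$rmsd100, rmsd100(fit$best_rmsd, 32))
  # incompatible fixed parameters are rejected before optimization
  expect_error(fit_structure(target, "coiled_coil",
                             fixed = list(n_chains = 3,
                                          n_residues = c(16, 16, 16)),
                             ranges = "dimer"),
               "does not match the target")
})

test_that("fitting a noisy dimer lands on the noise floor", {
  clean <- build_coiled_coil(crick_params(2, superhelix_radius = 4.5,
                                          pitch = 120, interface_angle = 5,
                                          n_residues = 16))
  noisy <- add_noise(clean, sigma = 0.3, seed = 7)
  fit <- fit_structure(noisy, "coiled_coil", ranges = "dimer",
                       cfg = optimizer_config(20, 50, seed = 2))
  expect_gt(fit$best_rmsd, 0.3 * sqrt(3) * 0.7)
  expect_lt(fit$best_rmsd, 0.3 * sqrt(3) * 1.3)
  # refitting the exact recovered model cannot be worse than the noisy fit:
  # its global optimum (RMSD 0) lies inside the search box
  refit <- fit_structure(fit$best_model, "coiled_coil", ranges = "dimer",
                         cfg = optimizer_config(20, 20, seed = 3))
  expect_lte(refit$best_rmsd, fit$best_rmsd + 1e-9)
})

test_that("median fit quality does not degrade with more generations", {
  target <- build_coiled_coil(crick_params(2, superhelix_radius = 4.5,
                                           pitch = 120, interface_angle = 5,
                                           n_residues = 12))
  best_at <- function(gens, seed) {
    fit_structure(target, "coiled_coil", ranges = "dimer",
                  cfg = optimizer_config(10, gens, seed))$best_rmsd
  }
  short <- vapply(1:5, function(s) best_at(10, s), numeric(1))
  long <- vapply(1:5, function(s) best_at(50, s), numeric(1))
  expect_lte(median(long), median(short))
})

test_that("HYP targets are treated as PRO during fitting", {
  target <- build_coiled_coil(crick_params(2, superhelix_radius = 4.5,
                                           pitch = 120, n_residues = 10))
  target$atoms$mol_code[target$atoms$res_seq == 3] <- "HYP"
  fit <- fit_structure(target, "coiled_coil", ranges = "dimer",
                       cfg = optimizer_config(8, 5, seed = 1))
  expect_true(is.finite(fit$best_rmsd))
})

test_that("a degenerate twist-free 2-repeat solenoid yields the rise", {
  target <- build_solenoid(solenoid_params(ankyrin_unit_truth(),
                                           n_repeats = 2, radius = 30,
                                           rise_per_repeat = 10,
                                           twist_per_repeat = 0))
  fit <- two_stage_solenoid_fit(target, 2,
                                default_ranges("ankyrin_unit"),
                                default_ranges("ankyrin_solenoid"),
                                cfg1 = optimizer_config(30, 30, seed = 5),
                                cfg2 = optimizer_config(30, 60, seed = 5))
  expect_equal(unname(fit$best_params[["rise_per_repeat"]]), 10,
               tolerance = 0.05)
  expect_s3_class(fit$stage1, "FitResult")
})

test_that("two-stage fit validates the repeat segmentation", {
  target <- build_coiled_coil(trimer_truth(10))   # 3 chains
  expect_error(two_stage_solenoid_fit(target, 2,
                                      default_ranges("ankyrin_unit"),
                                      default_ranges("ankyrin_solenoid")),
               "not divisible")
})

test_that("packaged default ranges match the published protocol", {
  radii <- list(dimer = c(3.5, 5.5), trimer = c(5.0, 7.0),
                tetramer = c(5.5, 8.5), pentamer = c(6.5, 9.5))
  for (set in names(radii)) {
    rs <- default_ranges(set)
    expect_identical(vapply(rs, `[[`, "", "name"),
                     c("superhelix_radius", "pitch", "interface_angle"))
    expect_equal(c(rs[[1]]$lower, rs[[1]]$upper), radii[[set]])
    expect_equal(c(rs[[2]]$lower, rs[[2]]$upper), c(50, 350))
    expect_equal(c(rs[[3]]$lower, rs[[3]]$upper), c(-20, 20))
  }
  col <- default_ranges("collagen")
  expect_equal(length(col), 9)
  zs <- col[[4]]
  expect_identical(zs$name, "z_shift_1")
  expect_equal(c(zs$lower, zs$upper), c(0.0, 6.2))
  unit <- default_ranges("ankyrin_unit")
  expect_equal(length(unit), 10)
  sol <- default_ranges("ankyrin_solenoid")
  expect_identical(vapply(sol, `[[`, "", "name"),
                   c("radius", "rise_per_repeat", "twist_per_repeat",
                     "unit_rotation"))
  expect_equal(c(sol[[1]]$lower, sol[[1]]$upper), c(25, 45))
  expect_equal(c(sol[[2]]$lower, sol[[2]]$upper), c(2, 18))
})

test_that("index-suffixed names merge into vector parameter fields", {
  merged <- parafold:::merge_params(list(n_chains = 3, z_shift = c(0, 0, 0)),
                                    list(z_shift_2 = 2.5, pitch = 140))
  expect_equal(merged$z_shift, c(0, 2.5, 0))
  expect_equal(merged$pitch, 140)
})
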