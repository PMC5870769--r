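# Coiled coils, tropocollagen, helix pairs, solenoids.

test_that("coiled-coil builds have the advertised counts", {
  cc <- build_coiled_coil(crick_params(3, superhelix_radius = 6.0,
                                       pitch = 150, interface_angle = 0,
                                       n_residues = 28))
  expect_equal(n_atoms(cc), 336)
  expect_identical(chain_ids(cc), c("A", "B", "C"))
  expect_equal(unname(vapply(c("A", "B", "C"),
                             function(ch) n_residues(cc, ch), integer(1))),
               c(28, 28, 28))
})

test_that("parallel Cn builds have exact rotational symmetry", {
  for (n in c(2, 3, 5)) {
    cc <- build_coiled_coil(crick_params(n, superhelix_radius = 6.0,
                                         pitch = 150, interface_angle = 7,
                                         n_residues = 20))
    a <- coords(get_polymer(cc, "A"))
    b <- coords(get_polymer(cc, "B"))
    expect_lt(max(abs(rotate(a, c(0, 0, 1), 360 / n) - b)), 1e-6)
  }
})

test_that("the built superhelix radius is recovered from the primitive", {
  cc <- build_coiled_coil(crick_params(3, superhelix_radius = 6.0,
                                       pitch = 150, interface_angle = 0,
                                       n_residues = 28))
  # interior primitive points average out the minor helix, exposing the
  # superhelical path at radius r
  pts <- primitive_of(get_polymer(cc, "A"))$points[4:25, ]
  expect_equal(mean(sqrt(pts[, 1]^2 + pts[, 2]^2)), 6.0, tolerance = 0.3)
})

test_that("z-shift, chain rotation and orientation act per chain", {
  p <- crick_params(2, superhelix_radius = 5, pitch = 120,
                    z_shift = c(0, 3.5), n_residues = 16)
  cc <- build_coiled_coil(p)
  za <- mean(coords(get_polymer(cc, "A"))[, 3])
  zb <- mean(coords(get_polymer(cc, "B"))[, 3])
  expect_equal(zb - za, 3.5, tolerance = 1e-6)
  anti <- build_coiled_coil(crick_params(2, superhelix_radius = 5,
                                         pitch = 120, n_residues = 16,
                                         orientation = c("parallel",
                                                         "antiparallel")))
  dirz <- function(ch) {
    ca <- coords(get_polymer(anti, ch))[get_polymer(anti, ch)$atoms$label ==
                                          "CA", ]
    fit_axis(ca)$direction[3]
  }
  expect_gt(dirz("A"), 0.9)
  expect_lt(dirz("B"), -0.9)
})

test_that("crick parameter validation names the offending parameter", {
  expect_error(crick_params(1, 6, 150), "n_chains")
  expect_error(crick_params(3, -2, 150), "superhelix_radius")
  expect_error(crick_params(3, 6, 0), "pitch")
  expect_error(crick_params(3, 6, 150, n_residues = 1), "n_residues")
  expect_error(crick_params(3, 6, 150, orientation = "sideways"),
               "orientation")
})

test_that("tropocollagen counts, stagger ordering and PPII torsions", {
  tc <- build_tropocollagen(collagen_truth(30))
  expect_equal(n_atoms(tc), 360)
  expect_equal(length(chain_ids(tc)), 3)
  z <- vapply(chain_ids(tc), function(ch) {
    pol <- get_polymer(tc, ch)
    mean(coords(pol)[pol$atoms$label == "CA", 3])
  }, numeric(1))
  expect_true(all(diff(z) > 0))            # staggered in z-shift order 0, 2.8, 5.6
  # supercoiling the PPII strand perturbs its torsions; the drift scales
  # with the superhelix pitch angle alpha (about alpha/2 empirically), so
  # bound it by alpha itself and anchor the straight build to the canon
  m <- measure_torsions(get_polymer(tc, "A"))
  tor <- helix_class("ppii")$torsions
  alpha_deg <- atan2(2 * pi * 3.0, 85) * 180 / pi   # ~12.5 degrees
  expect_lt(max(abs(m$phi[5:25] - tor[["phi"]])), alpha_deg)
  expect_lt(max(abs(m$psi[5:25] - tor[["psi"]])), alpha_deg)
  m0 <- measure_torsions(build_helix("ppii", 30))
  expect_lt(max(abs(m0$phi[5:25] - tor[["phi"]])), 3)
  expect_lt(max(abs(m0$psi[5:25] - tor[["psi"]])), 3)
  expect_error(build_tropocollagen(crick_params(2, 3, 85)), "3 chains")
})

test_that("helix pairs place parallel axes at the requested separation", {
  hp <- build_helix_pair(helix_pair_params(axis_distance = c(3, 3),
                                           helix_lengths = c(12, 12)))
  axA <- fit_axis(coords(get_polymer(hp, "A"))[
    get_polymer(hp, "A")$atoms$label == "CA", ])
  axB <- fit_axis(coords(get_polymer(hp, "B"))[
    get_polymer(hp, "B")$atoms$label == "CA", ])
  expect_gt(abs(sum(axA$direction * axB$direction)), 0.999)  # parallel
  expect_equal(sqrt(sum((axA$point - axB$point)^2)), 6, tolerance = 0.2)
})

test_that("splay changes the inter-axis angle by the splay difference", {
  angle_between <- function(p) {
    hp <- build_helix_pair(p)
    ax <- lapply(c("A", "B"), function(ch) {
      pol <- get_polymer(hp, ch)
      fit_axis(coords(pol)[pol$atoms$label == "CA", ])$direction
    })
    acos(min(1, abs(sum(ax[[1]] * ax[[2]])))) * 180 / pi
  }
  a0 <- angle_between(helix_pair_params(axis_distance = c(3, 3),
                                        helix_lengths = c(14, 14)))
  a10 <- angle_between(helix_pair_params(axis_distance = c(3, 3),
                                         splay = c(0, 10),
                                         helix_lengths = c(14, 14)))
  expect_equal(a10 - a0, 10, tolerance = 1)
})

test_that("equal helix-pair parameters sit symmetrically about the axis", {
  hp <- build_helix_pair(helix_pair_params(axis_distance = c(4, 4),
                                           helix_lengths = c(10, 10)))
  # the two placements are mirror sites (x = -4 and x = +4); with equal
  # parameters the actual helices are related by the pure translation
  # (+8, 0, 0), since an alpha helix is chiral and cannot equal its own
  # reflection atom-for-atom
  a <- coords(get_polymer(hp, "A"))
  b <- coords(get_polymer(hp, "B"))
  expect_lt(max(abs(sweep(a, 2, c(8, 0, 0), `+`) - b)), 1e-9)
  # interior primitive points recover the mirror-site x offsets
  px <- function(ch) {
    mean(primitive_of(get_polymer(hp, ch))$points[3:8, 1])
  }
  expect_equal(px("A"), -4, tolerance = 0.2)
  expect_equal(px("B"), 4, tolerance = 0.2)
  expect_error(helix_pair_params(axis_distance = c(1, 2, 3)), "length 2")
  expect_error(helix_pair_params(axis_distance = c(1, 2),
                                 helix_lengths = c(1, 10)), "helix_lengths")
})

test_that("solenoid counts, screw-transform constancy and twist-0 stacking", {
  sol <- build_solenoid(solenoid_params(ankyrin_unit_truth(), n_repeats = 5,
                                        radius = 32, rise_per_repeat = 10,
                                        twist_per_repeat = 12))
  expect_equal(length(chain_ids(sol)), 10)
  expect_equal(n_residues(sol), 100)
  # consecutive repeats related by one fixed screw transform
  rep_xyz <- function(k) {
    ids <- chain_ids(sol)[(2 * k - 1):(2 * k)]
    sol$xyz[sol$atoms$chain %in% ids, ]
  }
  s12 <- superpose(rep_xyz(1), rep_xyz(2))
  for (k in 2:4) {
    s <- superpose(rep_xyz(k), rep_xyz(k + 1))
    expect_lt(s$rmsd, 1e-6)
    expect_lt(max(abs(s$rotation - s12$rotation)), 1e-6)
    expect_lt(max(abs(s$translation - s12$translation)), 1e-6)
  }
  # twist 0: repeat centroids stack collinearly, spaced by the rise
  stack <- build_solenoid(solenoid_params(ankyrin_unit_truth(),
                                          n_repeats = 4, radius = 30,
                                          rise_per_repeat = 7,
                                          twist_per_repeat = 0))
  cen <- t(vapply(1:4, function(k) {
    ids <- chain_ids(stack)[(2 * k - 1):(2 * k)]
    colMeans(stack$xyz[stack$atoms$chain %in% ids, ])
  }, numeric(3)))
  expect_lt(max(abs(diff(cen[, 1]))), 1e-6)
  expect_lt(max(abs(diff(cen[, 2]))), 1e-6)
  expect_equal(unname(diff(cen[, 3])), rep(7, 3), tolerance = 1e-6)
})

test_that("solenoid handedness flips the applied twist", {
  p <- solenoid_params(ankyrin_unit_truth(), n_repeats = 3, radius = 30,
                       rise_per_repeat = 8, twist_per_repeat = 15)
  right <- build_solenoid(p)
  p$handedness <- "left"
  left <- build_solenoid(p)
  p$handedness <- "right"; p$twist_per_repeat <- -15
  expect_equal(coords(left), coords(build_solenoid(p)), tolerance = 1e-12)
  expect_gt(backbone_rmsd(left, right)$rmsd, 0.5)  # genuinely different
})

test_that("solenoid validation and chain-alphabet exhaustion error", {
  expect_error(solenoid_params(ankyrin_unit_truth(), 1, 30, 8, 15),
               "n_repeats")
  expect_error(solenoid_params(ankyrin_unit_truth(), 3, -1, 8, 15),
               "radius")
  big <- solenoid_params(helix_pair_params(axis_distance = c(2, 2),
                                           helix_lengths = c(2, 2)),
                         n_repeats = 32, radius = 30, rise_per_repeat = 5,
                         twist_per_repeat = 10)
  expect_error(build_solenoid(big), "64 chains")
})

test_that("builders are deterministic: identical parameters, identical bits", {
  p <- trimer_truth(20)
  expect_identical(coords(build_coiled_coil(p)), coords(build_coiled_coil(p)))
  sp <- ankyrin_solenoid_truth(3)
  expect_identical(coords(build_solenoid(sp)), coords(build_solenoid(sp)))
})

test_that("build_specification dispatches by name and rejects unknowns", {
  m <- build_specification("coiled_coil",
                           list(n_chains = 2, superhelix_radius = 5,
                                pitch = 120, n_residues = 10))
  expect_equal(n_atoms(m), 80)
  expect_setequal(specification_names(),
                  c("coiled_coil", "tropocollagen", "helix_pair",
                    "solenoid", "dna_duplex"))
  expect_error(build_specification("nope", list()), "unknown specification")
})
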