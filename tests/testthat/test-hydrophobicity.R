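single_atom_structure <- function(resname = "DUM", element = "C") {
  point_atoms_structure(data.frame(name = "C1", element = element,
                                   resname = resname, resid = 1L,
                                   x = 0, y = 0, z = 0))
}

test_that("probe volumes reproduce closed-form sphere measures on a grid", {
  st <- single_atom_structure()
  pv <- build_probe_volume(st, 1, radius = 5, spacing = 0.25, exclude_vdw = FALSE)
  expect_equal(pv$volume, 4 / 3 * pi * 125, tolerance = 0.01)

  # two co-centered spheres measure as one (union idempotence)
  st2 <- point_atoms_structure(data.frame(
    name = c("C1", "C2"), element = "C", resname = "DUM", resid = c(1L, 2L),
    x = 0, y = 0, z = 0))
  pv2 <- build_probe_volume(st2, 1:2, radius = 5, spacing = 0.25, exclude_vdw = FALSE)
  expect_equal(pv2$volume, pv$volume, tolerance = 1e-9)

  # disjoint spheres add
  st3 <- point_atoms_structure(data.frame(
    name = c("C1", "C2"), element = "C", resname = "DUM", resid = c(1L, 2L),
    x = c(0, 30), y = 0, z = 0))
  pv3 <- build_probe_volume(st3, 1:2, radius = 5, spacing = 0.25, exclude_vdw = FALSE)
  expect_equal(pv3$volume, 2 * 4 / 3 * pi * 125, tolerance = 0.01)

  # van der Waals exclusion removes protein-interior volume
  pvx <- build_probe_volume(st, 1, radius = 5, spacing = 0.25, exclude_vdw = TRUE)
  expect_equal(pvx$volume, 4 / 3 * pi * (125 - 1.7^3), tolerance = 0.01)
  expect_error(build_probe_volume(st, 99), class = "erbb_usage_error")
})

test_that("water counts match planted occupancies exactly", {
  # 3 waters inside a 5 A probe, 5 outside
  wdf <- data.frame(name = "O", element = "O", resname = "HOH",
                    resid = 1:8, chain = "W",
                    x = c(1, -2, 0.5, 9, 12, -8, 10, 11),
                    y = c(0.5, 1, -1, 9, 0, 8, -10, 12), z = 0)
  pdf <- data.frame(name = "C1", element = "C", resname = "DUM", resid = 99L,
                    chain = "A", x = 0, y = 0, z = 0)
  top <- point_atoms_structure(rbind(pdf, wdf))
  traj <- trajectory_ensemble(top, list(coords(top)))
  probe <- build_probe_volume(top, 99, radius = 5, spacing = 0.5, exclude_vdw = FALSE)
  expect_equal(water_counts(traj, probe)$counts, 3)

  # generator-registered occupancy matches package counting exactly
  gen <- make_water_box(list(box = c(20, 20, 20), density = 0.04,
                             n_frames = 20, seed = 5))
  big <- build_probe_volume(
    point_atoms_structure(data.frame(name = "C1", element = "C", resname = "DUM",
                                     resid = 1L, x = 10, y = 10, z = 10)),
    1, radius = 25, spacing = 1, exclude_vdw = FALSE)
  # a sphere that covers the whole box counts every in-box water
  cnt <- local({
    top <- gen$traj$topology
    traj <- trajectory_ensemble(top, gen$traj$frames)
    water_counts(traj, big)$counts
  })
  expect_equal(cnt, gen$ground_truth$counts)
  expect_error(water_counts(trajectory_ensemble(single_atom_structure(),
                                                list(matrix(0, 1, 3))), big),
               class = "erbb_input_error")
})

test_that("the chi statistic follows its defining arithmetic", {
  s <- water_count_series(c(4, 6, 4, 6), volume = 100)
  expect_equal(chi_statistic(s), 4.0)
  expect_equal(chi_statistic(water_count_series(rep(7, 10), 50)), 0)
  expect_error(chi_statistic(water_count_series(rep(0, 10), 50)),
               class = "erbb_statistics_error")
  # Poisson counts: chi -> Vol/<N> (variance = mean)
  set.seed(2)
  n <- rpois(20000, 40)
  expect_equal(chi_statistic(water_count_series(n, 1000)),
               1000 / mean(n), tolerance = 0.05)
})

test_that("chi is frame-order invariant and linear in the probe volume", {
  set.seed(3)
  n <- rpois(500, 30)
  a <- chi_statistic(water_count_series(n, 200))
  expect_equal(chi_statistic(water_count_series(rev(n), 200)), a)
  expect_equal(chi_statistic(water_count_series(n, 400)), 2 * a)
})

test_that("bulk reference is seeded, reproducible and validates placement", {
  gen <- make_water_box(list(box = c(24, 24, 24), density = 0.0334,
                             n_frames = 150, seed = 11))
  st <- gen$traj$topology
  probe_at <- point_atoms_structure(data.frame(
    name = "C1", element = "C", resname = "DUM", resid = 1L,
    x = 12, y = 12, z = 12))
  probe <- build_probe_volume(probe_at, 1, radius = 5, spacing = 0.4,
                              exclude_vdw = FALSE)
  b1 <- bulk_reference(gen$traj, probe, n_samples = 10, min_dist = 0, seed = 99)
  b2 <- bulk_reference(gen$traj, probe, n_samples = 10, min_dist = 0, seed = 99)
  expect_identical(b1, b2)
  expect_error(bulk_reference(gen$traj, probe, n_samples = 2, min_dist = 500, seed = 1),
               class = "erbb_placement_error")
  # pure-water box: a fixed probe agrees with the bulk ensemble within 3 SE
  raw <- chi_statistic(water_counts(gen$traj, probe))
  expect_lt(abs(normalized_chi(raw, b1) - 1), 0.35)
})

test_that("normalization maps bulk-like fluctuations to 1 and orders regimes", {
  expect_equal(normalized_chi(3.2, 3.2), 1)
  expect_error(normalized_chi(1, 0), class = "erbb_statistics_error")

  mkchi <- function(model) {
    gen <- make_water_box(list(box = c(22, 22, 22), density = 0.0334,
                               n_frames = 400, seed = 17, model = model))
    probe_at <- point_atoms_structure(data.frame(
      name = "C1", element = "C", resname = "DUM", resid = 1L,
      x = 11, y = 11, z = 11))
    probe <- build_probe_volume(probe_at, 1, radius = 6, spacing = 0.4,
                                exclude_vdw = FALSE)
    raw <- chi_statistic(water_counts(gen$traj, probe))
    bulk_pois <- probe$volume / mean(water_counts(gen$traj, probe)$counts)
    normalized_chi(raw, bulk_pois)
  }
  expect_lt(mkchi("suppressed"), 0.85)
  expect_gt(mkchi("enhanced"), 1.3)
})

test_that("Shrake-Rupley SASA matches closed forms and burial limits", {
  lone <- single_atom_structure(resname = "ALA")
  expect_equal(region_sasa(lone, 1), 4 * pi * 3.1^2, tolerance = 0.01)

  two_far <- point_atoms_structure(data.frame(
    name = c("C1", "C2"), element = "C", resname = "ALA", resid = c(1L, 2L),
    x = c(0, 100), y = 0, z = 0))
  expect_equal(region_sasa(two_far, 1:2), 2 * 4 * pi * 3.1^2, tolerance = 0.01)

  # an atom enclosed by a dense shell has essentially no accessible surface
  pts <- sphere_pts <- local({
    i <- seq_len(200) - 0.5
    phi <- acos(1 - 2 * i / 200); th <- pi * (1 + sqrt(5)) * i
    cbind(3 * sin(phi) * cos(th), 3 * sin(phi) * sin(th), 3 * cos(phi))
  })
  shell <- point_atoms_structure(data.frame(
    name = "C", element = "C", resname = "ALA",
    resid = c(1L, rep(2L, nrow(pts))),
    x = c(0, pts[, 1]), y = c(0, pts[, 2]), z = c(0, pts[, 3])))
  expect_lt(region_sasa(shell, 1), 1)
  expect_error(region_sasa(lone, integer(0)), class = "erbb_usage_error")
})

test_that("quadrant classification covers the plane with the documented tie rule", {
  b <- c(600, 1)
  expect_equal(classify_quadrant(700, 1.4, b), "II")  # fragile: high chi, high SASA
  expect_equal(classify_quadrant(500, 1.4, b), "IV")  # hydrophobically favorable
  expect_equal(classify_quadrant(700, 0.6, b), "I")   # hydrophilically favorable
  expect_equal(classify_quadrant(500, 0.6, b), "III")
  expect_equal(classify_quadrant(600, 1, b), "I")     # double boundary -> I
  # classification changes only across boundaries
  eps <- 1e-9
  expect_equal(classify_quadrant(600 + eps, 1 + eps, b), "II")
  expect_equal(classify_quadrant(600 - eps, 1 + eps, b), "IV")
  expect_equal(classify_quadrant(600 - eps, 1 - eps, b), "III")
  rec <- hydrophobicity_point("sys", "C-spine", 4, 2, 550, boundaries = b)
  expect_equal(rec$chi_norm, 2)
  expect_equal(rec$quadrant, "IV")
})
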