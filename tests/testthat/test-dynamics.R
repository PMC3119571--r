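test_that("Kabsch superposition recovers exact rigid motions", {
  set.seed(11)
  ref <- matrix(rnorm(15), 5, 3)
  fit0 <- superpose(ref, ref)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_lt(fit0$rmsd, 1e-10)

  R <- rotation_z(90)
  mob <- sweep(ref %*% R, 2, c(3, 4, 0), `+`)
  fit <- superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
})

test_that("Kabsch is never worse than a 1-degree brute-force rotation grid", {
  # planar toy: the optimal rotation lies in the grid's search plane
  set.seed(21)
  ref <- cbind(matrix(rnorm(8), 4, 2), 0)
  mob <- sweep(ref %*% rotation_z(37.3), 2, c(1, -2, 0), `+`)
  mob[1, 1] <- mob[1, 1] + 0.4   # non-rigid perturbation
  grid_best <- min(vapply(seq(0, 359, by = 1), function(deg) {
    rot <- mob %*% rotation_z(deg)
    rot <- sweep(rot, 2, colMeans(rot) - colMeans(ref))
    sqrt(mean(rowSums((rot - ref)^2)))
  }, numeric(1)))
  expect_lte(superpose(mob, ref)$rmsd, grid_best + 1e-12)
})

test_that("degenerate selections raise geometry errors", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line + 1), class = "erbb_geometry_error")
  expect_error(superpose(line[1:2, ], line[1:2, ]), class = "erbb_geometry_error")
})

test_that("frame-wise RMSD removes rigid motion and matches a numeric oracle", {
  st <- make_toy_kinase(20, seed = 7)
  base <- coords(st)
  static <- trajectory_ensemble(st, list(base, base, base))
  expect_equal(rmsd_series(static, base), c(0, 0, 0), tolerance = 1e-10)

  set.seed(4)
  rigid <- trajectory_ensemble(st, lapply(1:4, function(i) random_rigid_motion(base)))
  expect_true(all(rmsd_series(rigid, base) < 1e-6))

  # single displaced atom: package result equals an independent numeric
  # optimisation over rigid transforms
  sq <- rbind(c(1, 1, 0), c(-1, 1, 0), c(-1, -1, 0), c(1, -1, 0))
  moved <- sq; moved[1, 3] <- 1
  oracle <- optim(rep(0, 6), function(p) {
    th <- p[1:3]
    Rx <- matrix(c(1,0,0, 0,cos(th[1]),-sin(th[1]), 0,sin(th[1]),cos(th[1])),3,3,byrow=TRUE)
    Ry <- matrix(c(cos(th[2]),0,sin(th[2]), 0,1,0, -sin(th[2]),0,cos(th[2])),3,3,byrow=TRUE)
    Rz <- matrix(c(cos(th[3]),-sin(th[3]),0, sin(th[3]),cos(th[3]),0, 0,0,1),3,3,byrow=TRUE)
    fitd <- sweep(moved %*% (Rx %*% Ry %*% Rz), 2, p[4:6], `+`)
    sqrt(mean(rowSums((fitd - sq)^2)))
  }, method = "BFGS")$value
  expect_equal(superpose(moved, sq)$rmsd, oracle, tolerance = 1e-5)
  # and is bounded by the translation-only closed form sqrt((1-1/N)/N)
  expect_lte(superpose(moved, sq)$rmsd, sqrt(3) / 4 + 1e-8)
})

test_that("RMSF is zero for static trajectories and recovers oscillation amplitudes", {
  st <- make_toy_kinase(20, seed = 2)
  base <- coords(st)
  static <- trajectory_ensemble(st, list(base, base, base, base))
  expect_true(all(rmsf_profile(static)$amplitude < 1e-10))

  # symmetric two-point stretch along the separation axis: no rigid component
  a <- 0.8
  ca <- which(st$atoms$name == "CA")
  i1 <- ca[3]; i2 <- ca[15]
  axis <- base[i2, ] - base[i1, ]; axis <- axis / sqrt(sum(axis^2))
  frames <- lapply(1:40, function(t) {
    f <- base
    s <- if (t %% 2 == 0) a else -a
    f[i1, ] <- f[i1, ] + s * axis
    f[i2, ] <- f[i2, ] - s * axis
    f
  })
  prof <- rmsf_profile(trajectory_ensemble(st, frames))
  r1 <- st$atoms$resid[i1]
  expect_equal(prof$amplitude[prof$residue_id == r1], a, tolerance = 0.03)
  expect_lt(max(prof$amplitude[!prof$residue_id %in% st$atoms$resid[c(i1, i2)]]), 0.05)
})

test_that("PCA recovers a planted mode and its time course", {
  st <- make_toy_kinase(30, seed = 8)
  pat <- planted_mode_pattern(st, 10:20, axis = 3)
  gen <- make_planted_mode_trajectory(st, list(
    n_frames = 300, seed = 1, noise_sigma = 0.002,
    modes = list(list(pattern = pat, amplitude = 2, period = 60))))
  res <- pca_fluctuations(gen$traj, selection = seq_len(n_atoms(st)))
  expect_gte(variance_explained(res, 1), 0.99)
  proj <- res$projections[, 1]
  expect_gte(abs(cor(proj, gen$ground_truth$series[[1]])), 0.999)
  # eigenvalue sum equals total positional variance
  expect_equal(sum(res$eigenvalues),
               sum(apply(res$projections, 2, function(x) mean(x^2))),
               tolerance = 1e-6)
})

test_that("two planted modes with 2:1 amplitudes give ~4:1 eigenvalues", {
  st <- make_toy_kinase(30, seed = 8)
  p1 <- planted_mode_pattern(st, 5:12, axis = 3)
  p2 <- planted_mode_pattern(st, 18:26, axis = 2)
  gen <- make_planted_mode_trajectory(st, list(
    n_frames = 2000, seed = 2, noise_sigma = 0.02,
    modes = list(list(pattern = p1, amplitude = 2, period = 97),
                 list(pattern = p2, amplitude = 1, period = 41))))
  res <- pca_fluctuations(gen$traj, selection = seq_len(n_atoms(st)))
  expect_equal(res$eigenvalues[1] / res$eigenvalues[2], 4, tolerance = 0.1)
})

test_that("pure-noise trajectories stay below the empirical spectral bound", {
  st <- make_toy_kinase(20, seed = 3)
  gen <- make_planted_mode_trajectory(st, list(
    n_frames = 400, seed = 5, noise_sigma = 0.3,
    modes = list(list(pattern = planted_mode_pattern(st, 5:6), amplitude = 1e-9,
                      period = 50))))
  res <- pca_fluctuations(gen$traj)
  p <- length(res$eigenvalues); n <- 400
  mp_bound <- (1 + sqrt(p / n))^2
  expect_lt(res$eigenvalues[1] / mean(res$eigenvalues), 1.6 * mp_bound)
})

test_that("variance_explained is monotone, bounded and validated", {
  st <- make_toy_kinase(20, seed = 3)
  gen <- make_planted_mode_trajectory(st, list(
    n_frames = 50, seed = 5, noise_sigma = 0.2,
    modes = list(list(pattern = planted_mode_pattern(st, 5:8), amplitude = 1,
                      period = 10))))
  res <- pca_fluctuations(gen$traj)
  k <- length(res$eigenvalues)
  fr <- vapply(seq_len(k), function(i) variance_explained(res, i), numeric(1))
  expect_equal(fr[k], 1)
  expect_true(all(diff(fr) >= -1e-12))
  expect_error(variance_explained(res, 0), class = "erbb_usage_error")
  expect_error(variance_explained(res, k + 1), class = "erbb_usage_error")
  expect_error(pca_fluctuations(trajectory_ensemble(st, gen$traj$frames[1:3])),
               class = "erbb_statistics_error")
})

test_that("fluctuation profiles export to the B-factor column", {
  st <- make_toy_kinase(20, seed = 3)
  prof <- data.frame(residue_id = unique(st$atoms$resid),
                     amplitude = seq_along(unique(st$atoms$resid)) * 0.1)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_fluctuation_pdb(st, prof, p)
  pdb <- bio3d::read.pdb(p)
  expect_equal(pdb$atom$b[1], 0.1, tolerance = 0.01)
})
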