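# Superposition, RMSD/RMSF and principal component analysis of C-alpha
# fluctuations. Covariances use population normalization (divide by the
# number of frames) so eigenvalue sums equal total positional variance and
# match the fluctuation formula used by the hydrophobicity module.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' the selected atoms of `mobile` and `reference`.
#'
#' @param mobile n x 3 coordinate matrix (Angstrom).
#' @param reference n x 3 coordinate matrix of the same shape.
#' @param selection integer atom indices used for the fit (default: all);
#'   at least 3 non-collinear atoms.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom, over the selection after transform). The transform
#'   maps mobile coordinates as `x %*% rotation + translation`.
#' @export
superpose <- function(mobile, reference, selection = seq_len(nrow(mobile))) {
  if (!all(dim(mobile) == dim(reference)))
    abort_shape("mobile is %d x %d but reference is %d x %d",
                nrow(mobile), ncol(mobile), nrow(reference), ncol(reference))
  if (length(selection) < 3) abort_geometry("selection needs at least 3 atoms")
  a <- mobile[selection, , drop = FALSE]
  b <- reference[selection, , drop = FALSE]
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  sv <- svd(crossprod(a0, b0))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    abort_geometry("degenerate (collinear) selection; rotation is not determined")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_vec <- cb - as.numeric(ca %*% R)
  fitted <- a %*% R
  fitted <- sweep(fitted, 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

apply_superposition <- function(x, fit) sweep(x %*% fit$rotation, 2, fit$translation, `+`)

#' Per-frame RMSD of a trajectory against a reference
#'
#' Each frame is rigid-body superposed onto the reference over the
#' selection before the deviation is measured, so rigid motion does not
#' contribute.
#'
#' @param traj TrajectoryEnsemble.
#' @param reference n_atoms x 3 matrix.
#' @param selection atom indices (default all).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference, selection = seq_len(n_atoms(traj$topology))) {
  vapply(traj$frames, function(f) superpose(f, reference, selection)$rmsd, numeric(1))
}

# Two-pass mean superposition: fit to frame 1, compute mean, re-fit to mean.
superpose_to_mean <- function(traj, selection) {
  frames <- traj$frames
  ref <- frames[[1]]
  pass <- function(frames, ref) {
    lapply(frames, function(f) apply_superposition(f, superpose(f, ref, selection)))
  }
  frames <- pass(frames, ref)
  mean1 <- Reduce(`+`, frames) / length(frames)
  frames <- pass(frames, mean1)
  mean2 <- Reduce(`+`, frames) / length(frames)
  list(frames = frames, mean = mean2)
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation about the mean structure after two-pass
#' mean superposition, reported per residue at the selected atoms
#' (conventionally the C-alphas).
#'
#' @param traj TrajectoryEnsemble.
#' @param selection atom indices to analyse (default: atoms named CA; if
#'   none, all atoms).
#' @return data.frame with columns `residue_id`, `amplitude` (Angstrom).
#' @export
rmsf_profile <- function(traj, selection = NULL) {
  top <- traj$topology
  if (is.null(selection)) {
    selection <- which(top$atoms$name == "CA")
    if (!length(selection)) selection <- seq_len(n_atoms(top))
  }
  if (!length(selection)) abort_usage("empty atom selection")
  sp <- superpose_to_mean(traj, selection)
  dev2 <- vapply(sp$frames, function(f) {
    rowSums((f[selection, , drop = FALSE] - sp$mean[selection, , drop = FALSE])^2)
  }, numeric(length(selection)))
  if (is.null(dim(dev2))) dev2 <- matrix(dev2, nrow = length(selection))
  amp <- sqrt(rowMeans(dev2))
  data.frame(residue_id = top$atoms$resid[selection], amplitude = amp)
}

#' Principal component analysis of positional fluctuations
#'
#' Frames are superposed on their mean (two-pass) over the selection; the
#' 3N x 3N covariance of the selected coordinates (population-normalised)
#' is diagonalised. Projections are centered frame coordinates on each
#' eigenvector.
#'
#' @param traj TrajectoryEnsemble with more than 3 frames.
#' @param selection atom indices (default: CA atoms; all atoms if no CA).
#' @return list of class `PCAResult`: `mean_coords` (n_sel x 3),
#'   `eigenvalues` (descending, Angstrom^2), `eigenvectors` (3 n_sel x
#'   n_modes, orthonormal columns), `projections` (n_frames x n_modes),
#'   `selection`, `residue_id`.
#' @export
pca_fluctuations <- function(traj, selection = NULL) {
  if (n_frames(traj) <= 3) abort_stat("PCA needs more than 3 frames")
  top <- traj$topology
  if (is.null(selection)) {
    selection <- which(top$atoms$name == "CA")
    if (!length(selection)) selection <- seq_len(n_atoms(top))
  }
  sp <- superpose_to_mean(traj, selection)
  X <- t(vapply(sp$frames, function(f) as.numeric(t(f[selection, , drop = FALSE])),
                numeric(3 * length(selection))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  covm <- crossprod(Xc) / nrow(Xc)          # population normalization
  eig <- eigen(covm, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  proj <- Xc %*% eig$vectors
  structure(list(
    mean_coords = matrix(mu, ncol = 3, byrow = TRUE),
    eigenvalues = ev,
    eigenvectors = eig$vectors,
    projections = proj,
    selection = selection,
    residue_id = top$atoms$resid[selection]
  ), class = "PCAResult")
}

#' Fraction of total variance captured by the top k modes
#'
#' @param pca PCAResult.
#' @param k number of leading eigenmodes, `1 <= k <= n_modes`.
#' @return fraction in [0, 1], non-decreasing in `k`.
#' @export
variance_explained <- function(pca, k) {
  n <- length(pca$eigenvalues)
  if (k < 1 || k > n) abort_usage("k = %d out of range 1..%d", k, n)
  sum(pca$eigenvalues[seq_len(k)]) / sum(pca$eigenvalues)
}

#' Per-residue amplitude of one eigenmode
#'
#' RMS displacement amplitude each selected atom contributes to a mode,
#' scaled by the mode's RMS projection so the value is in Angstrom.
#'
#' @param pca PCAResult.
#' @param mode mode index.
#' @return data.frame with `residue_id`, `amplitude`.
#' @export
mode_amplitude_profile <- function(pca, mode = 1) {
  n <- length(pca$eigenvalues)
  if (mode < 1 || mode > n) abort_usage("mode %d out of range 1..%d", mode, n)
  v <- matrix(pca$eigenvectors[, mode], ncol = 3, byrow = TRUE)
  amp <- sqrt(rowSums(v^2)) * sqrt(pca$eigenvalues[mode])
  data.frame(residue_id = pca$residue_id, amplitude = amp)
}

#' Export a fluctuation profile as a color-codable PDB
#'
#' Writes the topology with per-atom amplitudes in the B-factor column so
#' large- and small-amplitude regions can be rendered as a color gradient.
#'
#' @param structure StructureModel.
#' @param profile data.frame from [rmsf_profile()] or
#'   [mode_amplitude_profile()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_fluctuation_pdb <- function(structure, profile, path) {
  b <- profile$amplitude[match(structure$atoms$resid, profile$residue_id)]
  b[is.na(b)] <- 0
  write_structure(structure, path, b = pmin(b, 999))
}
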