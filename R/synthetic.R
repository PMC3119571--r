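# Synthetic-data generators. Every generator is a pure function of
# (recipe, seed) and returns its ground truth alongside the data, so each
# analysis path can be tested against known answers.

#' Toy kinase structure
#'
#' A poly-alanine chain with an ideal-helix segment labeled "alphaC", a
#' loop segment labeled "A-loop", and a Lys/Glu residue pair positioned
#' in salt-bridge contact. Deterministic for a given seed.
#'
#' @param n_residues chain length (at least 20).
#' @param seed integer seed.
#' @return StructureModel with attribute `regions` (list: `alphaC`,
#'   `A_loop`, `salt_bridge_pair` residue ids).
#' @export
make_toy_kinase <- function(n_residues = 40, seed = 1) {
  if (n_residues < 20) abort_usage("toy kinase needs at least 20 residues")
  local_seed(seed, {
    helix <- seq(max(3, floor(n_residues * 0.2)), floor(n_residues * 0.35))
    aloop <- seq(floor(n_residues * 0.5), floor(n_residues * 0.7))
    lys_res <- helix[ceiling(length(helix) / 2)]
    glu_res <- aloop[ceiling(length(aloop) / 2)]
    ca <- matrix(0, n_residues, 3)
    for (i in seq_len(n_residues)) {
      if (i %in% helix) {
        k <- i - helix[1]
        ca[i, ] <- c(2.3 * cos(k * 100 * pi / 180) + 3.8 * helix[1],
                     2.3 * sin(k * 100 * pi / 180), 1.5 * k)
      } else {
        ca[i, ] <- c(3.8 * i, 1.2 * (i %% 2), 0)
      }
    }
    ca <- ca + matrix(stats::rnorm(3 * n_residues, sd = 0.05), ncol = 3)
    rows <- list(); serial <- 0L
    add <- function(res, resname, name, element, xyz) {
      serial <<- serial + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        serial = serial, name = name, element = element, resname = resname,
        resid = res, chain = "A", x = xyz[1], y = xyz[2], z = xyz[3])
    }
    for (i in seq_len(n_residues)) {
      resname <- if (i == lys_res) "LYS" else if (i == glu_res) "GLU" else "ALA"
      add(i, resname, "N", "N", ca[i, ] + c(-1.2, 0.6, 0))
      add(i, resname, "CA", "C", ca[i, ])
      add(i, resname, "C", "C", ca[i, ] + c(1.2, 0.6, 0))
      add(i, resname, "O", "O", ca[i, ] + c(1.3, 1.8, 0))
      add(i, resname, "CB", "C", ca[i, ] + c(0, -1.5, 0.4))
    }
    # side chains for the planted salt bridge: NZ placed 3.0 A from OE1
    glu_ca <- ca[glu_res, ]
    oe1 <- glu_ca + c(0, -3.0, 1.0)
    for (r in rows) NULL
    add(glu_res, "GLU", "CD", "C", glu_ca + c(0, -2.4, 0.2))
    add(glu_res, "GLU", "OE1", "O", oe1)
    add(glu_res, "GLU", "OE2", "O", glu_ca + c(0.8, -3.2, -0.2))
    add(lys_res, "LYS", "CE", "C", oe1 + c(0, -0.8, 3.6))
    add(lys_res, "LYS", "NZ", "N", oe1 + c(0, 0, 3.0))
    atoms <- do.call(rbind, rows)
    out <- structure_model(atoms, label = sprintf("toy-kinase-%d", n_residues))
    attr(out, "regions") <- list(alphaC = helix, A_loop = aloop,
                                 salt_bridge_pair = sort(c(lys_res, glu_res)))
    out
  })
}

#' Displacement pattern localized on a set of residues
#'
#' Unit-norm n_atoms x 3 pattern displacing the C-alpha atoms of the
#' given residues along one axis; a building block for planted-mode
#' trajectory recipes.
#'
#' @param structure StructureModel.
#' @param residues residue ids carrying the displacement.
#' @param axis 1, 2 or 3 (x, y, z).
#' @return n_atoms x 3 matrix with unit Frobenius norm.
#' @export
planted_mode_pattern <- function(structure, residues, axis = 1) {
  at <- structure$atoms
  pat <- matrix(0, nrow(at), 3)
  sel <- which(at$resid %in% residues & at$name == "CA")
  if (!length(sel)) abort_usage("no CA atoms in the requested residues")
  pat[sel, axis] <- 1
  pat / sqrt(sum(pat^2))
}

#' Trajectory with planted low-frequency modes plus isotropic noise
#'
#' Frame t is `base + sum_m amplitude_m * sin(2 pi t / period_m) *
#' pattern_m + noise`. Patterns must be mutually orthogonal so the
#' planted modes are the exact principal components in the noise-free
#' limit.
#'
#' @param structure StructureModel providing the base coordinates.
#' @param recipe list with `n_frames`, `modes` (list of lists with
#'   `pattern` (n_atoms x 3), `amplitude` (Angstrom), `period` (frames)),
#'   `noise_sigma` (Angstrom), `seed`.
#' @return list with `traj` (TrajectoryEnsemble) and `ground_truth`
#'   (patterns, amplitudes, periods, per-mode time series).
#' @export
make_planted_mode_trajectory <- function(structure, recipe) {
  nf <- recipe$n_frames
  modes <- recipe$modes
  base <- coords(structure)
  for (m in modes) {
    if (!all(dim(m$pattern) == dim(base)))
      abort_usage("mode pattern dimensions do not match the structure")
    if (m$amplitude <= 0) abort_usage("mode amplitudes must be positive")
  }
  if (length(modes) > 1) {
    for (i in seq_along(modes)) for (j in seq_along(modes)) {
      if (i < j && abs(sum(modes[[i]]$pattern * modes[[j]]$pattern)) > 1e-8)
        abort_usage("planted mode patterns must be mutually orthogonal")
    }
  }
  local_seed(recipe$seed %||% 1, {
    series <- lapply(modes, function(m)
      m$amplitude * sin(2 * pi * seq_len(nf) / m$period))
    frames <- lapply(seq_len(nf), function(t) {
      f <- base
      for (k in seq_along(modes)) f <- f + series[[k]][t] * modes[[k]]$pattern
      if ((recipe$noise_sigma %||% 0) > 0)
        f <- f + matrix(stats::rnorm(length(f), sd = recipe$noise_sigma), ncol = 3)
      f
    })
    list(traj = trajectory_ensemble(structure, frames),
         ground_truth = list(
           patterns = lapply(modes, `[[`, "pattern"),
           amplitudes = vapply(modes, `[[`, numeric(1), "amplitude"),
           periods = vapply(modes, `[[`, numeric(1), "period"),
           series = series))
  })
}

#' Water box with controlled count-fluctuation statistics
#'
#' Ideal-gas water frames: the number of in-box waters per frame is drawn
#' from the chosen fluctuation model and positions are resampled uniformly
#' and independently each frame. `poisson` gives variance = mean;
#' `suppressed` draws from a binomial over a fixed pool (variance < mean,
#' the hydrophilic-like signature); `enhanced` draws from a two-state
#' Poisson mixture (variance > mean, the hydrophobic-like signature).
#' Waters beyond the per-frame count are parked far outside the box so
#' the atom count is constant across frames.
#'
#' @param recipe list: `box` (length-3, Angstrom), `density` (per
#'   Angstrom^3, default 0.0334), `model` ("poisson", "suppressed",
#'   "enhanced"), `n_frames`, `seed`; `mix_delta` (default 0.3) sets the
#'   enhanced-mixture spread.
#' @return list with `traj` (waters-only TrajectoryEnsemble, box on the
#'   topology) and `ground_truth` (per-frame in-box counts, expected
#'   mean, variance-to-mean ratio of the model).
#' @export
make_water_box <- function(recipe) {
  box <- recipe$box
  density <- recipe$density %||% 0.0334
  model <- recipe$model %||% "poisson"
  nf <- recipe$n_frames
  lambda <- density * prod(box)
  if (lambda < 100) abort_usage("recipe yields fewer than 100 expected waters")
  local_seed(recipe$seed %||% 1, {
    counts <- switch(model,
      poisson = stats::rpois(nf, lambda),
      suppressed = stats::rbinom(nf, size = round(2 * lambda), prob = 0.5),
      enhanced = {
        delta <- recipe$mix_delta %||% 0.3
        lo <- stats::rpois(nf, lambda * (1 - delta))
        hi <- stats::rpois(nf, lambda * (1 + delta))
        ifelse(stats::runif(nf) < 0.5, lo, hi)
      },
      abort_usage("unknown fluctuation model '%s'", model))
    n_max <- max(counts)
    atoms <- data.frame(serial = seq_len(n_max), name = "O", element = "O",
                        resname = "HOH", resid = seq_len(n_max), chain = "W",
                        x = 0, y = 0, z = 0)
    park <- 1e5
    frames <- lapply(seq_len(nf), function(t) {
      n <- counts[t]
      f <- matrix(park, n_max, 3)
      if (n > 0) {
        f[seq_len(n), ] <- cbind(stats::runif(n, 0, box[1]),
                                 stats::runif(n, 0, box[2]),
                                 stats::runif(n, 0, box[3]))
      }
      f
    })
    first <- frames[[1]]
    atoms$x <- first[, 1]; atoms$y <- first[, 2]; atoms$z <- first[, 3]
    top <- structure_model(atoms, box = box, label = sprintf("waterbox-%s", model))
    vmr <- switch(model, poisson = 1, suppressed = 0.5,
                  enhanced = 1 + (recipe$mix_delta %||% 0.3)^2 * lambda)
    list(traj = trajectory_ensemble(top, frames),
         ground_truth = list(counts = counts, expected_mean = lambda,
                             variance_to_mean = vmr, model = model))
  })
}

#' Fixture structure with independent Lys/Glu pairs
#'
#' One Lys and one Glu residue per pair, each pair isolated from the
#' others, with the Lys placed so its NZ can be toggled in and out of
#' salt-bridge contact with the Glu OE1.
#'
#' @param n_pairs number of pairs.
#' @param contact NZ-OE1 distance in the contact state (Angstrom).
#' @return StructureModel with attribute `pairs` (list of residue id
#'   pairs, Glu first).
#' @export
make_salt_bridge_fixture <- function(n_pairs = 1, contact = 3.0) {
  rows <- list(); serial <- 0L
  add <- function(res, resname, name, element, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = element, resname = resname,
      resid = res, chain = "A", x = xyz[1], y = xyz[2], z = xyz[3])
  }
  pairs <- list()
  for (p in seq_len(n_pairs)) {
    ox <- (p - 1) * 40
    glu <- 2L * p - 1L; lys <- 2L * p
    add(glu, "GLU", "CA", "C", c(ox, 0, 0))
    add(glu, "GLU", "CD", "C", c(ox, 1.8, 0))
    add(glu, "GLU", "OE1", "O", c(ox, 3.0, 0))
    add(glu, "GLU", "OE2", "O", c(ox + 1, 3.2, 0))
    add(lys, "LYS", "CA", "C", c(ox, 3.0 + contact + 3, 0))
    add(lys, "LYS", "CE", "C", c(ox, 3.0 + contact + 1.4, 0))
    add(lys, "LYS", "NZ", "N", c(ox, 3.0 + contact, 0))
    pairs[[p]] <- c(glu, lys)
  }
  out <- structure_model(do.call(rbind, rows), label = "salt-bridge-fixture")
  attr(out, "pairs") <- pairs
  out
}

#' Trajectory with planted interaction survival fractions
#'
#' For each planted residue pair and frame, the Lys side chain is placed
#' in contact (NZ 3.0 A from OE1) or displaced out of contact according
#' to an independent Bernoulli draw at the pair's target survival
#' fraction. Ground-truth per-frame states are returned.
#'
#' @param structure StructureModel from [make_salt_bridge_fixture()] (or
#'   any structure whose planted pairs are Glu/Lys with CD-OE1/CE-NZ side
#'   chains).
#' @param recipe list: `pairs` (list of lists with `pair` = c(glu_res,
#'   lys_res), `survival` in [0, 1]), `n_frames`, `seed`.
#' @return list with `traj` and `ground_truth` (matrix n_pairs x n_frames
#'   of planted states, target survivals).
#' @export
make_planted_interaction_traj <- function(structure, recipe) {
  at <- structure$atoms
  nf <- recipe$n_frames
  for (pr in recipe$pairs) {
    if (pr$survival < 0 || pr$survival > 1) abort_usage("survival targets must be in [0, 1]")
    if (!all(pr$pair %in% at$resid))
      abort_lookup("pair (%d, %d) not resolvable in structure", pr$pair[1], pr$pair[2])
  }
  base <- coords(structure)
  local_seed(recipe$seed %||% 1, {
    states <- matrix(FALSE, length(recipe$pairs), nf)
    for (k in seq_along(recipe$pairs)) {
      s <- recipe$pairs[[k]]$survival
      states[k, ] <- if (s >= 1) TRUE else if (s <= 0) FALSE else
        stats::runif(nf) < s
    }
    frames <- lapply(seq_len(nf), function(t) {
      f <- base
      for (k in seq_along(recipe$pairs)) {
        if (!states[k, t]) {
          lys <- recipe$pairs[[k]]$pair[2]
          mv <- which(at$resid == lys)
          f[mv, 2] <- f[mv, 2] + 8   # swing the Lys side chain away
        }
      }
      f
    })
    list(traj = trajectory_ensemble(structure, frames),
         ground_truth = list(states = states,
                             survivals = vapply(recipe$pairs, `[[`, numeric(1), "survival"),
                             pairs = lapply(recipe$pairs, `[[`, "pair")))
  })
}

#' Noisy time courses from the signaling model
#'
#' Simulates the model, samples the observed species at the requested
#' times, and multiplies each observation by an independent lognormal
#' factor with the given coefficient of variation.
#'
#' @param model ModelSpec.
#' @param observed character vector of species names.
#' @param noise_cv lognormal sdlog (0 = exact).
#' @param replicates number of replicate datasets.
#' @param seed integer seed.
#' @param times observation times, minutes.
#' @return list with `times`, `data` (list of time x species matrices),
#'   `truth` (noise-free matrix and the model's parameter table).
#' @export
make_signaling_dataset <- function(model, observed, noise_cv = 0.05,
                                   replicates = 3, seed = 1,
                                   times = seq(0, 60, by = 5)) {
  if (noise_cv < 0) abort_usage("noise_cv must be non-negative")
  res <- simulate_model(model, t_end = max(times), dt = min(diff(times)))
  clean <- vapply(observed, function(s)
    stats::approx(res$times, res$state[, s], xout = times)$y,
    numeric(length(times)))
  colnames(clean) <- observed
  local_seed(seed, {
    data <- lapply(seq_len(replicates), function(r) {
      if (noise_cv == 0) clean else
        clean * matrix(stats::rlnorm(length(clean), 0, noise_cv), nrow(clean))
    })
    list(times = times, data = data,
         truth = list(clean = clean, params = model$params))
  })
}
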