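# Water-density-fluctuation hydrophobicity: probe observation volumes,
# per-frame water counts, the normalized chi statistic, Shrake-Rupley
# solvent accessible surface area, and the quadrant classification of
# (SASA, chi) points.

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Build a probe observation volume over a region
#'
#' The volume of interest is the union of spheres of given radius centered
#' on the heavy atoms of the region's residues, optionally excluding any
#' point inside a protein heavy-atom van der Waals sphere. The volume is
#' estimated on a regular grid.
#'
#' @param structure StructureModel.
#' @param region_residues integer residue ids defining the region.
#' @param radius sphere radius, Angstrom (default 5.5).
#' @param spacing grid spacing, Angstrom (default 0.25).
#' @param exclude_vdw subtract protein-interior grid points (default TRUE).
#' @return list of class `ProbeVolume`: `region`, `centers` (k x 3),
#'   `radius`, `spacing`, `volume` (Angstrom^3).
#' @export
build_probe_volume <- function(structure, region_residues, radius = 5.5,
                               spacing = 0.25, exclude_vdw = TRUE) {
  at <- structure$atoms
  sel <- at$resid %in% region_residues & !is_water_resname(at$resname) &
    toupper(at$element) != "H"
  if (!any(sel)) abort_usage("region has no heavy atoms in the structure")
  centers <- as.matrix(at[sel, c("x", "y", "z")])
  prot <- at[!is_water_resname(at$resname) & toupper(at$element) != "H", ]
  vol <- grid_union_volume(centers, radius, spacing,
                           exclude = if (exclude_vdw) as.matrix(prot[, c("x", "y", "z")]) else NULL,
                           exclude_r = if (exclude_vdw) vdw_radius(prot$element) else NULL)
  structure(list(region = paste(range(region_residues), collapse = "-"),
                 centers = centers, radius = radius, spacing = spacing,
                 volume = vol),
            class = "ProbeVolume")
}

# Volume of a union of equal spheres minus excluded spheres, on a grid.
grid_union_volume <- function(centers, radius, spacing, exclude = NULL, exclude_r = NULL) {
  lo <- apply(centers, 2, min) - radius - spacing
  hi <- apply(centers, 2, max) + radius + spacing
  ax <- lapply(1:3, function(k) seq(lo[k], hi[k], by = spacing))
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  inside <- logical(nx * ny * nz)
  mark <- function(flag, cen, r, value) {
    r2 <- r^2
    ix <- which(abs(ax[[1]] - cen[1]) <= r)
    iy <- which(abs(ax[[2]] - cen[2]) <= r)
    iz <- which(abs(ax[[3]] - cen[3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) return(flag)
    dx2 <- (ax[[1]][ix] - cen[1])^2
    dy2 <- (ax[[2]][iy] - cen[2])^2
    dz2 <- (ax[[3]][iz] - cen[3])^2
    loc <- outer(dx2, dy2, `+`)
    for (k in seq_along(iz)) {
      hit <- loc + dz2[k] <= r2
      if (any(hit)) {
        idx <- (iz[k] - 1L) * nx * ny + outer(ix, (iy - 1L) * nx, `+`)[hit]
        flag[idx] <- value
      }
    }
    flag
  }
  for (i in seq_len(nrow(centers))) inside <- mark(inside, centers[i, ], radius, TRUE)
  if (!is.null(exclude)) {
    for (i in seq_len(nrow(exclude))) inside <- mark(inside, exclude[i, ], exclude_r[i], FALSE)
  }
  sum(inside) * spacing^3
}

water_oxygen_indices <- function(structure) {
  at <- structure$atoms
  which(is_water_resname(at$resname) & toupper(at$element) == "O")
}

count_in_spheres <- function(xyz, frame_id, nf, centers, radius) {
  r2 <- radius^2
  hit <- logical(nrow(xyz))
  for (i in seq_len(nrow(centers))) {
    hit <- hit | (dist2_to_point(xyz, centers[i, ]) <= r2)
  }
  tabulate(frame_id[hit], nbins = nf)
}

#' Construct a water-count series
#' @param counts non-negative integer counts per frame.
#' @param volume probe volume Vol_N, Angstrom^3.
#' @param label source label.
#' @export
water_count_series <- function(counts, volume, label = "") {
  if (any(counts < 0)) abort_input("water counts must be non-negative")
  if (volume <= 0) abort_input("probe volume must be positive")
  structure(list(counts = as.numeric(counts), volume = volume, label = label),
            class = "WaterCountSeries")
}

#' Count waters inside a probe volume, per frame
#'
#' Waters are counted by their oxygen position only (one integer per
#' molecule). A water oxygen is inside the probe when it falls within any
#' of the probe's spheres.
#'
#' @param traj TrajectoryEnsemble whose topology identifies waters.
#' @param probe ProbeVolume.
#' @return [water_count_series()] of length n_frames.
#' @export
water_counts <- function(traj, probe) {
  wi <- water_oxygen_indices(traj$topology)
  if (!length(wi)) abort_input("topology contains no waters")
  nf <- n_frames(traj)
  xyz <- do.call(rbind, lapply(traj$frames, function(f) f[wi, , drop = FALSE]))
  frame_id <- rep(seq_len(nf), each = length(wi))
  counts <- count_in_spheres(xyz, frame_id, nf, probe$centers, probe$radius)
  water_count_series(counts, probe$volume, label = "probe")
}

#' Raw water-density-fluctuation statistic
#'
#' chi = Vol_N * (<N^2> - <N>^2) / <N>^2 with population (divide-by-n)
#' moments. For Poisson counts chi tends to Vol_N / <N>, the inverse
#' density, which is what the bulk reference divides out.
#'
#' @param series WaterCountSeries.
#' @return chi in Angstrom^3.
#' @export
chi_statistic <- function(series) {
  m <- mean(series$counts)
  if (m <= 0) abort_stat("mean water count is zero; chi is undefined")
  v <- mean(series$counts^2) - m^2
  series$volume * v / m^2
}

local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Bulk-water reference chi
#'
#' Mean raw chi over randomly placed congruent copies of the probe whose
#' sphere centers all stay at least `min_dist` from any protein heavy atom
#' and inside the box. Seeded and reproducible.
#'
#' @param traj TrajectoryEnsemble with a box on its topology.
#' @param probe ProbeVolume template.
#' @param n_samples number of random placements (default 50).
#' @param min_dist minimum distance from protein heavy atoms, Angstrom.
#' @param seed integer seed.
#' @return mean raw chi (Angstrom^3) across placements.
#' @export
bulk_reference <- function(traj, probe, n_samples = 50, min_dist = 8, seed = 1) {
  box <- traj$topology$box
  if (is.null(box)) abort_input("bulk reference needs a periodic box on the topology")
  at <- traj$topology$atoms
  prot <- at[!is_water_resname(at$resname) & toupper(at$element) != "H", ]
  prot_xyz <- as.matrix(prot[, c("x", "y", "z")])
  cen0 <- sweep(probe$centers, 2, colMeans(probe$centers))
  ext <- max(sqrt(rowSums(cen0^2))) + probe$radius
  if (any(box / 2 < ext))
    abort_placement("probe extent %.1f A does not fit the %.1f A box", ext, min(box))
  if (min_dist >= max(box))
    abort_placement("exclusion distance %.1f A exceeds the box", min_dist)
  wi <- water_oxygen_indices(traj$topology)
  if (!length(wi)) abort_input("topology contains no waters")
  nf <- n_frames(traj)
  xyz <- do.call(rbind, lapply(traj$frames, function(f) f[wi, , drop = FALSE]))
  frame_id <- rep(seq_len(nf), each = length(wi))
  local_seed(seed, {
    chis <- numeric(n_samples)
    for (s in seq_len(n_samples)) {
      ok <- FALSE
      for (try in 1:200) {
        rot <- random_rotation()
        cen <- cen0 %*% rot
        shift <- runif(3, ext, box - ext)
        if (any(ext >= box - ext)) break
        cen <- sweep(cen, 2, shift, `+`)
        if (nrow(prot_xyz)) {
          mind2 <- min(vapply(seq_len(nrow(cen)), function(i)
            min(dist2_to_point(prot_xyz, cen[i, ])), numeric(1)))
          if (mind2 < min_dist^2) next
        }
        ok <- TRUE
        break
      }
      if (!ok) abort_placement("could not place a bulk probe %.1f A from the protein", min_dist)
      counts <- count_in_spheres(xyz, frame_id, nf, cen, probe$radius)
      chis[s] <- chi_statistic(water_count_series(counts, probe$volume, "bulk"))
    }
    mean(chis)
  })
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Normalize a raw chi by the bulk reference
#'
#' chi_norm of 1 marks a neutral region; values above 1 signal enhanced
#' water-density fluctuations, the signature of a more hydrophobic
#' surface, and values below 1 signal suppressed (hydrophilic-like)
#' fluctuations.
#'
#' @param raw raw chi (Angstrom^3).
#' @param bulk bulk reference chi (> 0).
#' @return dimensionless chi_norm.
#' @export
normalized_chi <- function(raw, bulk) {
  if (bulk <= 0) abort_stat("bulk chi must be positive")
  raw / bulk
}

# Deterministic unit sphere points (golden-spiral), used by Shrake-Rupley.
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area of a region (Shrake-Rupley)
#'
#' SASA of the region's atoms computed in the context of all protein heavy
#' atoms, with a 1.4 Angstrom probe by default. For a trajectory the value
#' is averaged over frames.
#'
#' @param x StructureModel or TrajectoryEnsemble.
#' @param region_residues residue ids of the region (default: all protein
#'   residues).
#' @param probe_radius solvent probe radius, Angstrom.
#' @param n_points test points per atom sphere (default 960).
#' @return mean SASA in Angstrom^2.
#' @export
region_sasa <- function(x, region_residues = NULL, probe_radius = 1.4, n_points = 960) {
  if (inherits(x, "TrajectoryEnsemble")) {
    vals <- vapply(x$frames, function(f)
      sasa_frame(x$topology, f, region_residues, probe_radius, n_points), numeric(1))
    return(mean(vals))
  }
  sasa_frame(x, coords(x), region_residues, probe_radius, n_points)
}

sasa_frame <- function(structure, xyz, region_residues, probe_radius, n_points) {
  at <- structure$atoms
  heavy <- !is_water_resname(at$resname) & toupper(at$element) != "H"
  idx <- which(heavy)
  if (!length(idx)) abort_usage("structure has no protein heavy atoms")
  if (is.null(region_residues)) region_residues <- unique(at$resid[idx])
  target <- idx[at$resid[idx] %in% region_residues]
  if (!length(target)) abort_usage("region has no atoms in the structure")
  pts <- sphere_points(n_points)
  radii <- vdw_radius(at$element) + probe_radius
  pos <- xyz[idx, , drop = FALSE]
  rads <- radii[idx]
  total <- 0
  for (a in target) {
    k <- match(a, idx)
    r <- rads[k]
    d2 <- dist2_to_point(pos, pos[k, ])
    nb <- which(d2 < (rads + r)^2 & d2 > 1e-12)
    test <- sweep(pts * r, 2, pos[k, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      exposed <- exposed & (dist2_to_point(test, pos[j, ]) > rads[j]^2)
      if (!any(exposed)) break
    }
    total <- total + sum(exposed) / n_points * 4 * pi * r^2
  }
  total
}

#' Classify a (SASA, chi_norm) point into a hydrophobicity quadrant
#'
#' Quadrant I: low chi, high SASA (hydrophilically favorable); II: high
#' chi, high SASA (fragile / perturbation sensitive); III: low chi, low
#' SASA; IV: high chi, low SASA (hydrophobically favorable). A point
#' exactly on a boundary goes to the lower quadrant index, so the double
#' boundary point is quadrant I.
#'
#' @param sasa_mean SASA, Angstrom^2.
#' @param chi_norm normalized fluctuation statistic.
#' @param boundaries length-2 vector `(sasa_split, chi_split)`; chi_split
#'   defaults to the neutral value 1.
#' @return one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @export
classify_quadrant <- function(sasa_mean, chi_norm, boundaries = c(NA, 1)) {
  sasa_split <- boundaries[1]; chi_split <- boundaries[2]
  if (is.na(sasa_split) || sasa_split <= 0 || chi_split <= 0)
    abort_usage("quadrant boundaries must be positive")
  high_chi <- chi_norm > chi_split     # tie goes to low chi (lower index)
  high_sasa <- sasa_mean >= sasa_split # tie goes to high SASA (lower index)
  if (high_sasa) { if (high_chi) "II" else "I" } else { if (high_chi) "IV" else "III" }
}

#' Assemble a hydrophobicity point record
#'
#' @param system system label (e.g. "EGFR-active-monomer").
#' @param region region label.
#' @param chi_raw raw chi, Angstrom^3.
#' @param chi_bulk bulk chi, Angstrom^3.
#' @param sasa_mean region SASA, Angstrom^2.
#' @param boundaries passed to [classify_quadrant()].
#' @return one-row data.frame (system, region, chi_raw, chi_bulk, chi_norm,
#'   sasa_mean, quadrant).
#' @export
hydrophobicity_point <- function(system, region, chi_raw, chi_bulk, sasa_mean,
                                 boundaries = c(NA, 1)) {
  cn <- normalized_chi(chi_raw, chi_bulk)
  data.frame(system = system, region = region, chi_raw = chi_raw,
             chi_bulk = chi_bulk, chi_norm = cn, sasa_mean = sasa_mean,
             quadrant = classify_quadrant(sasa_mean, cn, boundaries),
             stringsAsFactors = FALSE)
}
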