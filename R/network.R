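# Per-frame salt-bridge / hydrogen-bond detection, survival fractions,
# persistent networks and network diffs. Pairs are residue-level: any
# qualifying atom pair counts once per frame.

#' Geometric contact criteria
#'
#' Defaults follow common literature conventions: charged-heavy-atom salt
#' bridge within 4.0 Angstrom; hydrogen bond with donor-acceptor heavy-atom
#' distance within 3.5 Angstrom and donor-hydrogen-acceptor angle of at
#' least 120 degrees (when hydrogens are absent, the acceptor-donor-
#' antecedent heavy-atom angle must be at least 90 degrees).
#'
#' @param salt_bridge_cutoff Angstrom.
#' @param hbond_distance_cutoff Angstrom (donor-acceptor heavy atoms).
#' @param hbond_angle_min degrees in (0, 180].
#' @return list of class `ContactCriteria`.
#' @export
contact_criteria <- function(salt_bridge_cutoff = 4.0,
                             hbond_distance_cutoff = 3.5,
                             hbond_angle_min = 120) {
  if (salt_bridge_cutoff <= 0 || hbond_distance_cutoff <= 0)
    abort_usage("contact cutoffs must be positive")
  if (hbond_angle_min <= 0 || hbond_angle_min > 180)
    abort_usage("hbond_angle_min must be in (0, 180]")
  structure(list(salt_bridge_cutoff = salt_bridge_cutoff,
                 hbond_distance_cutoff = hbond_distance_cutoff,
                 hbond_angle_min = hbond_angle_min),
            class = "ContactCriteria")
}

BASIC_ATOMS  <- list(LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"))
ACIDIC_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

DONOR_ATOMS <- list(
  "*"  = "N",                      # backbone amide of any residue
  SER = "OG", THR = "OG1", TYR = "OH", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), TRP = "NE1"
)
ACCEPTOR_ATOMS <- list(
  "*"  = "O",                      # backbone carbonyl
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)
# covalent antecedent of each donor heavy atom, for the hydrogen-free proxy
DONOR_ANTECEDENT <- c(N = "CA", OG = "CB", OG1 = "CB", OH = "CZ", NZ = "CE",
                      NE = "CD", NH1 = "CZ", NH2 = "CZ", ND2 = "CG", NE2 = "CD",
                      ND1 = "CG", NE1 = "CD1")

match_atoms <- function(atoms, vocab) {
  hit <- rep(FALSE, nrow(atoms))
  for (res in names(vocab)) {
    if (res == "*") hit <- hit | atoms$name %in% vocab[[res]]
    else hit <- hit | (atoms$resname == res & atoms$name %in% vocab[[res]])
  }
  which(hit & !is_water_resname(atoms$resname))
}

resolve_frame <- function(structure, frame) {
  if (is.null(frame)) coords(structure) else frame
}

dedup_pairs <- function(ri, rj) {
  if (!length(ri)) return(data.frame(res_i = integer(0), res_j = integer(0)))
  lo <- pmin(ri, rj); hi <- pmax(ri, rj)
  u <- unique(data.frame(res_i = lo, res_j = hi))
  u[order(u$res_i, u$res_j), , drop = FALSE]
}

#' Detect salt bridges in one frame
#'
#' A residue pair is reported when any basic nitrogen (Lys NZ; Arg
#' NE/NH1/NH2; His ND1/NE2) lies within the salt-bridge cutoff of any
#' acidic oxygen (Asp OD1/OD2; Glu OE1/OE2).
#'
#' @param structure StructureModel.
#' @param frame optional n_atoms x 3 coordinate matrix (default: the
#'   structure's own coordinates).
#' @param criteria ContactCriteria.
#' @return data.frame of deduplicated residue pairs (`res_i` < `res_j`).
#' @export
detect_salt_bridges <- function(structure, frame = NULL, criteria = contact_criteria()) {
  xyz <- resolve_frame(structure, frame)
  at <- structure$atoms
  bi <- match_atoms(at, BASIC_ATOMS)
  ai <- match_atoms(at, ACIDIC_ATOMS)
  if (!length(bi) || !length(ai)) return(dedup_pairs(integer(0), integer(0)))
  cut2 <- criteria$salt_bridge_cutoff^2
  ri <- integer(0); rj <- integer(0)
  for (b in bi) {
    d2 <- dist2_to_point(xyz[ai, , drop = FALSE], xyz[b, ])
    hit <- ai[d2 <= cut2]
    hit <- hit[at$resid[hit] != at$resid[b] | at$chain[hit] != at$chain[b]]
    if (length(hit)) { ri <- c(ri, rep(at$resid[b], length(hit))); rj <- c(rj, at$resid[hit]) }
  }
  dedup_pairs(ri, rj)
}

hbond_angle_ok <- function(structure, xyz, d_idx, a_idx, criteria) {
  at <- structure$atoms
  d <- xyz[d_idx, ]; a <- xyz[a_idx, ]
  same_res <- at$resid == at$resid[d_idx] & at$chain == at$chain[d_idx]
  hyd <- which(same_res & grepl("^[0-9]*H", at$name))
  if (length(hyd)) {
    hyd <- hyd[dist2_to_point(xyz[hyd, , drop = FALSE], d) <= 1.25^2]
  }
  ang <- function(p, q, r) {  # angle at q, degrees
    v1 <- p - q; v2 <- r - q
    cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  }
  if (length(hyd)) {
    return(any(vapply(hyd, function(h) ang(d, xyz[h, ], a) >= criteria$hbond_angle_min,
                      logical(1))))
  }
  ante_name <- DONOR_ANTECEDENT[at$name[d_idx]]
  if (is.na(ante_name)) return(TRUE)
  ante <- which(same_res & at$name == ante_name)
  if (!length(ante)) return(TRUE)
  ang(a, d, xyz[ante[1], ]) >= 90
}

#' Detect hydrogen bonds in one frame
#'
#' Donor-acceptor heavy-atom pairs (backbone N/O plus polar side-chain
#' atoms) within the distance cutoff and satisfying the angle criterion:
#' donor-hydrogen-acceptor when hydrogens are present, otherwise the
#' acceptor-donor-antecedent proxy at 90 degrees.
#'
#' @inheritParams detect_salt_bridges
#' @return data.frame of deduplicated residue pairs.
#' @export
detect_hbonds <- function(structure, frame = NULL, criteria = contact_criteria()) {
  xyz <- resolve_frame(structure, frame)
  at <- structure$atoms
  di <- match_atoms(at, DONOR_ATOMS)
  ai <- match_atoms(at, ACCEPTOR_ATOMS)
  if (!length(di) || !length(ai)) return(dedup_pairs(integer(0), integer(0)))
  cut2 <- criteria$hbond_distance_cutoff^2
  ri <- integer(0); rj <- integer(0)
  for (d in di) {
    d2 <- dist2_to_point(xyz[ai, , drop = FALSE], xyz[d, ])
    hit <- ai[d2 <= cut2]
    hit <- hit[at$resid[hit] != at$resid[d] | at$chain[hit] != at$chain[d]]
    for (a in hit) {
      if (hbond_angle_ok(structure, xyz, d, a, criteria)) {
        ri <- c(ri, at$resid[d]); rj <- c(rj, at$resid[a])
      }
    }
  }
  dedup_pairs(ri, rj)
}

detect_frame_pairs <- function(structure, frame, criteria) {
  sb <- detect_salt_bridges(structure, frame, criteria)
  hb <- detect_hbonds(structure, frame, criteria)
  key_sb <- paste(sb$res_i, sb$res_j)
  key_hb <- paste(hb$res_i, hb$res_j)
  all <- union(key_sb, key_hb)
  list(pairs = all, salt = key_sb)
}

#' Per-frame presence series for every observed interaction
#'
#' Runs both detectors on every frame and returns, per residue pair, the
#' boolean presence trace and the per-frame salt-bridge votes.
#'
#' @param traj TrajectoryEnsemble.
#' @param criteria ContactCriteria.
#' @return list with `pairs` (data.frame res_i, res_j), `present` (n_pairs x
#'   n_frames logical), `salt` (same shape: salt-bridge detector fired).
#' @export
interaction_series <- function(traj, criteria = contact_criteria()) {
  per_frame <- lapply(traj$frames, function(f)
    detect_frame_pairs(traj$topology, f, criteria))
  keys <- sort(unique(unlist(lapply(per_frame, `[[`, "pairs"))))
  nf <- length(per_frame)
  present <- matrix(FALSE, length(keys), nf)
  saltm <- matrix(FALSE, length(keys), nf)
  for (t in seq_len(nf)) {
    present[, t] <- keys %in% per_frame[[t]]$pairs
    saltm[, t] <- keys %in% per_frame[[t]]$salt
  }
  ids <- do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  list(pairs = data.frame(res_i = ids[, 1], res_j = ids[, 2]),
       present = present, salt = saltm)
}

#' Survival fraction of one interaction over a trajectory
#'
#' @param traj TrajectoryEnsemble.
#' @param pair length-2 integer vector of residue ids.
#' @param criteria ContactCriteria.
#' @param detector `"any"` (either detector), `"salt-bridge"` or `"h-bond"`.
#' @return fraction of frames in [0, 1] in which the pair is present.
#' @export
survival_fraction <- function(traj, pair, criteria = contact_criteria(),
                              detector = c("any", "salt-bridge", "h-bond")) {
  detector <- match.arg(detector)
  if (!all(pair %in% traj$topology$atoms$resid))
    abort_lookup("pair (%d, %d) not resolvable in topology", pair[1], pair[2])
  key <- paste(min(pair), max(pair))
  hits <- vapply(traj$frames, function(f) {
    if (detector == "salt-bridge") {
      sb <- detect_salt_bridges(traj$topology, f, criteria)
      key %in% paste(sb$res_i, sb$res_j)
    } else if (detector == "h-bond") {
      hb <- detect_hbonds(traj$topology, f, criteria)
      key %in% paste(hb$res_i, hb$res_j)
    } else {
      key %in% detect_frame_pairs(traj$topology, f, criteria)$pairs
    }
  }, logical(1))
  mean(hits)
}

#' Persistent hydrophilic interaction network of a trajectory
#'
#' Every residue pair observed by either detector whose survival fraction
#' reaches the threshold. A pair is typed salt-bridge when the salt-bridge
#' detector fires in at least half of its present frames, h-bond otherwise.
#'
#' @param traj TrajectoryEnsemble.
#' @param criteria ContactCriteria.
#' @param threshold persistence threshold on the survival fraction
#'   (default 0.6).
#' @return data.frame with `res_i`, `res_j`, `bond_type`,
#'   `survival_fraction`, `persistent`.
#' @export
persistent_network <- function(traj, criteria = contact_criteria(), threshold = 0.6) {
  if (threshold > 1) warning("threshold > 1 can never be met; returning empty network")
  ser <- interaction_series(traj, criteria)
  if (!nrow(ser$pairs))
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      bond_type = character(0), survival_fraction = numeric(0),
                      persistent = logical(0)))
  surv <- rowMeans(ser$present)
  salt_share <- rowSums(ser$salt & ser$present) / pmax(rowSums(ser$present), 1)
  out <- data.frame(ser$pairs,
                    bond_type = ifelse(salt_share >= 0.5, "salt-bridge", "h-bond"),
                    survival_fraction = surv,
                    persistent = surv >= threshold)
  out[out$persistent, , drop = FALSE]
}

#' Compare two persistent networks
#'
#' Partitions the union of pairs into retained / lost / gained (relative to
#' network `a`) and reports the survival delta (b - a) for shared pairs.
#'
#' @param a,b data.frames as returned by [persistent_network()].
#' @return list of class `NetworkComparison` with `retained`, `lost`,
#'   `gained` data.frames; `retained` carries `survival_a`, `survival_b`,
#'   `delta`.
#' @export
compare_networks <- function(a, b) {
  ka <- paste(a$res_i, a$res_j); kb <- paste(b$res_i, b$res_j)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    abort_input("duplicate pairs within one network")
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  retained <- data.frame(a[ia, c("res_i", "res_j", "bond_type")],
                         survival_a = a$survival_fraction[ia],
                         survival_b = b$survival_fraction[ib])
  retained$delta <- retained$survival_b - retained$survival_a
  structure(list(
    retained = retained,
    lost = a[!(ka %in% kb), , drop = FALSE],
    gained = b[!(kb %in% ka), , drop = FALSE]
  ), class = "NetworkComparison")
}
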