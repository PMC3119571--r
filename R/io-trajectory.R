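#' Construct a TrajectoryEnsemble
#'
#' The unit of all time statistics: an ordered set of coordinate frames over
#' a fixed topology. Frames are n_atoms x 3 matrices in Angstrom.
#'
#' @param topology StructureModel describing every frame's atoms.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param timestep picoseconds between consecutive frames (> 0).
#' @return object of class `TrajectoryEnsemble`.
#' @export
trajectory_ensemble <- function(topology, frames, timestep = 1) {
  if (!inherits(topology, "StructureModel")) abort_input("topology must be a StructureModel")
  if (!length(frames)) abort_input("a trajectory needs at least one frame")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3L)
      abort_shape("frame %d is not an n x 3 matrix", i)
    if (nrow(f) != na)
      abort_shape("frame %d has %d atoms but topology has %d", i, nrow(f), na)
  }
  if (!is.numeric(timestep) || timestep <= 0) abort_input("timestep must be > 0")
  structure(list(topology = topology, frames = frames, timestep = timestep),
            class = "TrajectoryEnsemble")
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  cat(sprintf("TrajectoryEnsemble: %d frames x %d atoms, dt = %g ps\n",
              n_frames(x), n_atoms(x$topology), x$timestep))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj TrajectoryEnsemble
#' @export
n_frames <- function(traj) length(traj$frames)

# ---- DCD (CHARMM binary trajectory) ------------------------------------
# Written with base writeBin; read back through bio3d::read.dcd. Single
# precision, so round trips are exact to well under 1e-3 Angstrom.

write_dcd <- function(frames, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  nfr <- length(frames)
  nat <- nrow(frames[[1]])
  rec <- function(writer) {
    # Fortran unformatted record: payload wrapped in byte counts
    raw <- writer()
    writeBin(length(raw), con, size = 4L, endian = "little")
    writeBin(raw, con)
    writeBin(length(raw), con, size = 4L, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nfr; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nfr
  icntrl[20] <- 24L   # CHARMM version stamp
  rec(function() c(charToRaw("CORD"), writeBin(icntrl, raw(), size = 4L, endian = "little")))
  title <- sprintf("%-80s", "erbbscale synthetic trajectory")
  rec(function() c(writeBin(1L, raw(), size = 4L, endian = "little"), charToRaw(title)))
  rec(function() writeBin(nat, raw(), size = 4L, endian = "little"))
  for (f in frames) {
    for (k in 1:3) rec(function() writeBin(as.numeric(f[, k]), raw(), size = 4L, endian = "little"))
  }
  invisible(path)
}

#' Read a coordinate trajectory
#'
#' Supported dialects: `"dcd"` (CHARMM/NAMD binary, via bio3d) and
#' `"multi-model-pdb"` (MODEL/ENDMDL blocks). Coordinates are returned in
#' Angstrom. The XTC dialect is recognised but not implemented.
#'
#' @param path trajectory file.
#' @param topology StructureModel whose atom count must match every frame.
#' @param dialect one of `"dcd"`, `"multi-model-pdb"`, `"xtc"`.
#' @param timestep picoseconds per frame stored on the result.
#' @return TrajectoryEnsemble with frames in file order.
#' @export
read_trajectory <- function(path, topology, dialect = c("dcd", "multi-model-pdb", "xtc"),
                            timestep = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort_input("file not found: %s", path)
  if (dialect == "xtc")
    abort_usage("the xtc dialect is not supported; convert to dcd or multi-model pdb")
  if (dialect == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    nat <- ncol(xyz) / 3L
    if (nat != n_atoms(topology))
      abort_shape("trajectory frames have %d atoms but topology has %d", nat, n_atoms(topology))
    frames <- lapply(seq_len(nrow(xyz)), function(i) matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  } else {
    lines <- readLines(path, warn = FALSE)
    bad <- check_pdb_coord_fields(lines)
    if (bad > 0L)
      abort_parse("malformed coordinate field at line %d of %s", bad, path)
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    nat <- ncol(xyz) / 3L
    if (nat != n_atoms(topology))
      abort_shape("trajectory frames have %d atoms but topology has %d", nat, n_atoms(topology))
    frames <- lapply(seq_len(nrow(xyz)), function(i) matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  }
  trajectory_ensemble(topology, frames, timestep = timestep)
}

#' Write a trajectory to disk
#'
#' @param traj TrajectoryEnsemble.
#' @param path output file.
#' @param dialect `"dcd"` or `"multi-model-pdb"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, dialect = c("dcd", "multi-model-pdb")) {
  dialect <- match.arg(dialect)
  if (dialect == "dcd") return(write_dcd(traj$frames, path))
  a <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(traj$topology$box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       traj$topology$box[1], traj$topology$box[2], traj$topology$box[3],
                       90, 90, 90), con)
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4), sprintf(" %-3s", a$name))
  for (i in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    f <- traj$frames[[i]]
    writeLines(sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       a$serial %% 100000L, name4, substr(a$resname, 1, 3),
                       substr(a$chain, 1, 1), a$resid %% 10000L,
                       f[, 1], f[, 2], f[, 3], 1, 0, substr(a$element, 1, 2)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
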