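#' Construct a StructureModel
#'
#' A `StructureModel` is the in-memory unit of all geometry in the package:
#' an ordered atom table plus an optional periodic box. Coordinates are
#' always in Angstrom. Residue numbering is taken verbatim from the source
#' file (author numbering) and never renumbered.
#'
#' @param atoms data.frame with columns `serial` (integer, unique), `name`
#'   (atom name), `element` (element symbol, non-empty), `resname` (3-letter
#'   residue code), `resid` (integer residue id), `chain` (single character),
#'   `x`, `y`, `z` (Angstrom, finite).
#' @param box optional numeric length-3 vector of box edge lengths (Angstrom,
#'   all > 0), or `NULL`.
#' @param label free-text label carried through reports.
#' @return object of class `StructureModel`.
#' @export
structure_model <- function(atoms, box = NULL, label = "") {
  req <- c("serial", "name", "element", "resname", "resid", "chain", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) abort_input("atom table missing columns: %s", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, req]
  if (anyDuplicated(atoms$serial)) abort_input("atom serials are not unique")
  if (any(!nzchar(atoms$element) | is.na(atoms$element)))
    abort_input("empty element symbol in atom table")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    abort_input("non-finite atom coordinates")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0))
      abort_input("box must be 3 positive lengths (Angstrom)")
  }
  structure(list(atoms = atoms, box = box, label = as.character(label)),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel '%s': %d atoms, %d residues%s\n",
              x$label, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid))),
              if (is.null(x$box)) "" else sprintf(", box %.1f x %.1f x %.1f A",
                                                  x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Number of atoms in a structure
#' @param x StructureModel
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' Atom coordinates as an n x 3 matrix (Angstrom)
#' @param x StructureModel
#' @export
coords <- function(x) as.matrix(x$atoms[, c("x", "y", "z")])

#' Logical mask of water atoms
#'
#' Waters are identified by residue name (HOH, WAT, TIP3, SOL).
#' @param x StructureModel
#' @export
water_mask <- function(x) is_water_resname(x$atoms$resname)

#' Count water residues in a structure
#' @param x StructureModel
#' @export
count_waters <- function(x) {
  w <- x$atoms[water_mask(x), ]
  if (!nrow(w)) return(0L)
  length(unique(paste(w$chain, w$resid)))
}

# Validate that every ATOM/HETATM line has parseable coordinate fields;
# returns the index of the first bad line or 0.
check_pdb_coord_fields <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) return(i)
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v)) return(i)
    }
  }
  0L
}

parse_cryst1 <- function(lines) {
  i <- grep("^CRYST1", lines)
  if (!length(i)) return(NULL)
  ln <- lines[i[1]]
  box <- suppressWarnings(as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                                       substr(ln, 25, 33))))
  if (any(is.na(box)) || any(box <= 0)) return(NULL)
  box
}

#' Read a protein structure file
#'
#' Parses PDB ATOM/HETATM records (via bio3d) into a [structure_model()].
#' Waters are retained; a CRYST1 record, if present, populates the box.
#' Alternate locations: blank or 'A' kept, others dropped, so the model is a
#' deterministic single conformer.
#'
#' @param path file path.
#' @param dialect file dialect; only `"pdb"` is supported.
#' @return StructureModel with atoms in file order.
#' @export
read_structure <- function(path, dialect = "pdb") {
  if (!identical(dialect, "pdb")) abort_usage("unknown structure dialect '%s'", dialect)
  if (!file.exists(path)) abort_input("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^(ATOM  |HETATM)", lines)))
    abort_input("empty input: no ATOM/HETATM records in %s", path)
  bad <- check_pdb_coord_fields(lines)
  if (bad > 0L)
    abort_parse("malformed coordinate field at line %d of %s: '%s'", bad, path, lines[bad])
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", "A")
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  guess <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", at$elety)), 1, 1))
  elem[is.na(elem) | !nzchar(elem)] <- guess[is.na(elem) | !nzchar(elem)]
  chain <- at$chain
  chain[is.na(chain)] <- " "
  structure_model(
    atoms = data.frame(serial = at$eleno, name = at$elety, element = elem,
                       resname = at$resid, resid = at$resno, chain = chain,
                       x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE),
    box = parse_cryst1(lines),
    label = tools::file_path_sans_ext(basename(path))
  )
}

#' Write a StructureModel as a PDB file
#'
#' @param x StructureModel.
#' @param path output file path.
#' @param b optional numeric per-atom values written to the B-factor column
#'   (used e.g. to export fluctuation amplitudes for structure coloring).
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, b = NULL) {
  a <- x$atoms
  if (is.null(b)) b <- rep(0, nrow(a))
  if (length(b) != nrow(a)) abort_shape("b has %d values for %d atoms", length(b), nrow(a))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(x$box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       x$box[1], x$box[2], x$box[3], 90, 90, 90), con)
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  sprintf(" %-3s", a$name))
  writeLines(sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                     a$serial %% 100000L, name4, substr(a$resname, 1, 3),
                     substr(a$chain, 1, 1), a$resid %% 10000L,
                     a$x, a$y, a$z, 1, b, substr(a$element, 1, 2)), con)
  writeLines("END", con)
  invisible(path)
}
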