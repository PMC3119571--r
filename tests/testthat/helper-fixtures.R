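# Shared fixtures built in code at test time.

# minimal hand-written PDB text (three atoms, one residue)
write_tiny_pdb <- function(path, cryst = NULL, bad_coord_line = FALSE) {
  lines <- character(0)
  if (!is.null(cryst))
    lines <- c(lines, sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                              cryst[1], cryst[2], cryst[3]))
  lines <- c(lines,
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C")
  if (bad_coord_line)
    lines[length(lines)] <-
      "ATOM      3  C   ALA A   1       xx.xxx   1.400   0.000  1.00  0.00           C"
  writeLines(c(lines, "END"), path)
  path
}

# structure with a single atom of a chosen residue/atom type at each point
point_atoms_structure <- function(df) {
  df$serial <- seq_len(nrow(df))
  df$chain <- df$chain %||% "A"
  structure_model(df[, c("serial", "name", "element", "resname", "resid",
                         "chain", "x", "y", "z")])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

random_rigid_motion <- function(xyz) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
                2*(x*y+w*z), 1 - 2*(x^2+z^2), 2*(y*z-w*x),
                2*(x*z-w*y), 2*(y*z+w*x), 1 - 2*(x^2+y^2)), 3, 3, byrow = TRUE)
  sweep(xyz %*% R, 2, runif(3, -20, 20), `+`)
}

# hand-built minimal ModelSpec for RHS/sensitivity unit tests
tiny_model <- function(species, reactions, params, composition = NULL) {
  spdf <- data.frame(name = names(species), initial = unname(species),
                     compartment = "cytosol", stringsAsFactors = FALSE)
  if (is.null(composition))
    composition <- matrix(0, 0, length(species), dimnames = list(NULL, names(species)))
  structure(list(species = spdf, reactions = reactions, params = params,
                 composition = composition,
                 metadata = list(units = "arbitrary", mutant = "none",
                                 egf_nM = 0, nrg_nM = 0, lapatinib_nM = 0)),
            class = "ModelSpec")
}

rxn <- function(reactants, products, rate_name, multiplier = 1) {
  tb <- function(x) { t <- table(x); stats::setNames(as.numeric(t), names(t)) }
  list(reactants = tb(reactants), products = tb(products),
       rate_name = rate_name, multiplier = multiplier)
}
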