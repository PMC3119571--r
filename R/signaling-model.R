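# Mass-action ODE model of the ErbB signaling network.
#
# Receptor layer: EGF binds EGFR; NRG-1beta binds ErbB3; ErbB2 is
# ligandless. Ligand-bound receptors homo- and heterodimerize (EGFR:EGFR,
# EGFR:ErbB2, ErbB2:ErbB3, ErbB3:ErbB3, and a weak EGFR:ErbB3 route),
# plus a slow constitutive ErbB2:ErbB3 dimerization. Trans-phosphorylation
# is per-protomer: each catalytically competent kinase phosphorylates its
# partner; ErbB3 is a weak kinase with a catalytic rate 1000-fold below
# the canonical members. Lapatinib binds EGFR and ErbB2 monomers, which
# still bind ligand and dimerize but contribute zero catalytic rate.
#
# EGFR C-terminal tail: Y1068 and Y1173 are tracked as explicit site pools
# phosphorylated by active EGFR-containing dimers; Grb2 (then GAB-1) docks
# on pY1068 and Shc docks on pY1173. Phosphorylated ErbB3 recruits PI3K
# directly. Downstream: Ras -> Raf -> MEK -> ERK from both tail arms, and
# PI3K -> PIP3 -> AKT with PTEN opposing; AKT activation requires PIP3
# binding of both AKT and PDK1. A generic ErbB phosphatase reverses
# receptor and tail phosphorylation. Phosphorylated dimers internalize.
#
# Units: molecules per cell; time in minutes. Ligand and inhibitor doses
# are given in nM and converted with a declared molecules-per-nM factor.

NM_TO_MOLEC <- 6000  # effective extracellular molecules per cell per nM

signaling_env <- new.env(parent = emptyenv())

#' Default signaling parameter set
#'
#' Rate constants, receptor surface levels and mutant profiles shipped
#' with the package (inst/extdata/params_default.yaml). The constants are
#' the package's own calibrated set (scripts/calibrate.R), not values from
#' the literature models the network topology follows.
#'
#' @return nested list (`params`, `initials`, `profiles`, `units`).
#' @export
default_signaling_parameters <- function() {
  if (is.null(signaling_env$defaults)) {
    signaling_env$defaults <- yaml::read_yaml(extdata_path("params_default.yaml"))
  }
  signaling_env$defaults
}

#' Mutant profile definitions
#'
#' Packaged profiles: `WT`, `L834R`, `del723-729insS`, `L834R/T766M`.
#' Each profile carries site-specific C-tail phosphorylation scale factors
#' for Y1068 and Y1173, an ATP-affinity scale on the EGFR catalytic rate,
#' and a ligand-independent activation (basal dimerization) rate.
#'
#' @param id profile id.
#' @return list with `y1068_scale`, `y1173_scale`, `atp_scale`,
#'   `basal_rate`.
#' @export
mutant_profile <- function(id) {
  prof <- default_signaling_parameters()$profiles[[id]]
  if (is.null(prof)) abort_config("unknown mutant profile '%s'", id)
  prof
}

#' Build the ErbB signaling model
#'
#' Assembles species, mass-action reactions and the parameter table from a
#' scenario configuration. NRG-bound species are only created when an NRG
#' dose and surface ErbB3 are present; inhibitor-bound species only when
#' the lapatinib dose is positive.
#'
#' @param config list with any of: `egf_nM`, `nrg_nM` (ligand doses),
#'   `lapatinib_nM`, `mutant` (profile id, default "WT"),
#'   `egfr_level`, `erbb2_level`, `erbb3_level` (surface receptors,
#'   molecules/cell), `egfr_expression` ("normal" or "over", the latter
#'   10x), `erbb3_fold`, `phosphatase_scale`, `params` (named overrides).
#' @return object of class `ModelSpec`.
#' @export
build_model <- function(config = list()) {
  def <- default_signaling_parameters()
  p <- unlist(def$params)
  if (!is.null(config$params)) p[names(config$params)] <- unlist(config$params)
  init <- unlist(def$initials)

  mutant <- config$mutant %||% "WT"
  prof <- mutant_profile(mutant)

  egf <- (config$egf_nM %||% 0) * NM_TO_MOLEC
  nrg <- (config$nrg_nM %||% 0) * NM_TO_MOLEC
  lap <- (config$lapatinib_nM %||% 0) * NM_TO_MOLEC
  over <- identical(config$egfr_expression %||% "normal", "over")
  r1_0 <- (config$egfr_level %||% init[["EGFR"]]) * if (over) 10 else 1
  r2_0 <- config$erbb2_level %||% init[["ErbB2"]]
  r3_0 <- (config$erbb3_level %||% init[["ErbB3"]]) * (config$erbb3_fold %||% 1)
  ptase_scale <- config$phosphatase_scale %||% 1

  has_erbb3 <- r3_0 > 0 && nrg > 0
  has_lap <- lap > 0

  # derived catalytic parameters
  p[["kcat_egfr"]] <- p[["kcat"]] * (prof$atp_scale %||% 1)
  p[["kcat_erbb2"]] <- p[["kcat"]]
  p[["kcat_erbb3"]] <- p[["kcat"]] / 1000   # weak ErbB3 kinase
  p[["kp68"]] <- p[["kp_tail"]] * prof$y1068_scale * (prof$atp_scale %||% 1)
  p[["kp73"]] <- p[["kp_tail"]] * prof$y1173_scale * (prof$atp_scale %||% 1)
  p[["kbasal"]] <- prof$basal_rate

  b <- new_model_builder()
  sp <- b$add_species; rx <- b$add_reaction

  # --- species ----------------------------------------------------------
  sp("EGF", egf, "membrane", c(EGF = 1))
  sp("R1", r1_0, "membrane", c(EGFR = 1))
  sp("R1L", 0, "membrane", c(EGFR = 1, EGF = 1))
  sp("R2", r2_0, "membrane", c(ErbB2 = 1))
  sp("D11_0", 0, "membrane", c(EGFR = 2, EGF = 2))
  sp("D11u_0", 0, "membrane", c(EGFR = 2))
  sp("D12_00", 0, "membrane", c(EGFR = 1, ErbB2 = 1, EGF = 1))
  sp("I11", 0, "cytosol", c(EGFR = 2, EGF = 2))
  sp("I11u", 0, "cytosol", c(EGFR = 2))
  sp("I12", 0, "cytosol", c(EGFR = 1, ErbB2 = 1, EGF = 1))
  if (has_lap) {
    sp("LAP", lap, "membrane", c(LAP = 1))
    sp("R1i", 0, "membrane", c(EGFR = 1, LAP = 1))
    sp("R1Li", 0, "membrane", c(EGFR = 1, EGF = 1, LAP = 1))
    sp("R2i", 0, "membrane", c(ErbB2 = 1, LAP = 1))
    sp("D11_1", 0, "membrane", c(EGFR = 2, EGF = 2, LAP = 1))
    sp("D11_2", 0, "membrane", c(EGFR = 2, EGF = 2, LAP = 2))
    sp("D11u_1", 0, "membrane", c(EGFR = 2, LAP = 1))
    sp("D11u_2", 0, "membrane", c(EGFR = 2, LAP = 2))
    sp("D12_10", 0, "membrane", c(EGFR = 1, ErbB2 = 1, EGF = 1, LAP = 1))
    sp("D12_01", 0, "membrane", c(EGFR = 1, ErbB2 = 1, EGF = 1, LAP = 1))
    sp("D12_11", 0, "membrane", c(EGFR = 1, ErbB2 = 1, EGF = 1, LAP = 2))
  }
  if (has_erbb3) {
    sp("NRG", nrg, "membrane", c(NRG = 1))
    sp("R3", r3_0, "membrane", c(ErbB3 = 1))
    sp("R3L", 0, "membrane", c(ErbB3 = 1, NRG = 1))
    sp("D23_0", 0, "membrane", c(ErbB2 = 1, ErbB3 = 1, NRG = 1))
    sp("D23p_0", 0, "membrane", c(ErbB2 = 1, ErbB3 = 1, NRG = 1))
    sp("D23p_0P", 0, "membrane", c(ErbB2 = 1, ErbB3 = 1, NRG = 1, PI3K = 1))
    sp("D23c_0", 0, "membrane", c(ErbB2 = 1, ErbB3 = 1))
    sp("D23cp_0", 0, "membrane", c(ErbB2 = 1, ErbB3 = 1))
    sp("D23cp_0P", 0, "membrane", c(ErbB2 = 1, ErbB3 = 1, PI3K = 1))
    sp("D33", 0, "membrane", c(ErbB3 = 2, NRG = 2))
    sp("D33p", 0, "membrane", c(ErbB3 = 2, NRG = 2))
    sp("D33pP", 0, "membrane", c(ErbB3 = 2, NRG = 2, PI3K = 1))
    sp("D13_0", 0, "membrane", c(EGFR = 1, ErbB3 = 1, NRG = 1))
    sp("D13p_0", 0, "membrane", c(EGFR = 1, ErbB3 = 1, NRG = 1))
    sp("D13p_0P", 0, "membrane", c(EGFR = 1, ErbB3 = 1, NRG = 1, PI3K = 1))
    sp("I23", 0, "cytosol", c(ErbB2 = 1, ErbB3 = 1, NRG = 1))
    sp("I23c", 0, "cytosol", c(ErbB2 = 1, ErbB3 = 1))
    sp("I33", 0, "cytosol", c(ErbB3 = 2, NRG = 2))
    sp("I13", 0, "cytosol", c(EGFR = 1, ErbB3 = 1, NRG = 1))
    if (has_lap) {
      sp("D23_1", 0, "membrane", c(ErbB2 = 1, ErbB3 = 1, NRG = 1, LAP = 1))
      sp("D23c_1", 0, "membrane", c(ErbB2 = 1, ErbB3 = 1, LAP = 1))
      sp("D13_1", 0, "membrane", c(EGFR = 1, ErbB3 = 1, NRG = 1, LAP = 1))
    }
  }
  # EGFR C-tail site pools (parallel bookkeeping of docking sites)
  sp("Y68", r1_0, "membrane", c(Y68 = 1))
  sp("pY68", 0, "membrane", c(Y68 = 1))
  sp("pY68G", 0, "membrane", c(Y68 = 1, Grb2 = 1))
  sp("Y73", r1_0, "membrane", c(Y73 = 1))
  sp("pY73", 0, "membrane", c(Y73 = 1))
  sp("pY73S", 0, "membrane", c(Y73 = 1, Shc = 1))
  sp("Grb2", init[["Grb2"]], "cytosol", c(Grb2 = 1))
  sp("Shc", init[["Shc"]], "cytosol", c(Shc = 1))
  sp("GAB1", init[["GAB1"]], "cytosol", c(GAB1 = 1))
  sp("GAB1m", 0, "membrane", c(GAB1 = 1))
  sp("PI3K", init[["PI3K"]], "cytosol", c(PI3K = 1))
  sp("GP", 0, "membrane", c(GAB1 = 1, PI3K = 1))
  sp("RasGDP", init[["Ras"]], "membrane", c(Ras = 1))
  sp("RasGTP", 0, "membrane", c(Ras = 1))
  sp("Raf", init[["Raf"]], "cytosol", c(Raf = 1))
  sp("Rafa", 0, "membrane", c(Raf = 1))
  sp("MEK", init[["MEK"]], "cytosol", c(MEK = 1))
  sp("MEKp", 0, "cytosol", c(MEK = 1))
  sp("ERK", init[["ERK"]], "cytosol", c(ERK = 1))
  sp("ERKp", 0, "cytosol", c(ERK = 1))
  sp("PIP2", init[["PIP2"]], "membrane", c(PIP = 1))
  sp("PIP3", 0, "membrane", c(PIP = 1))
  sp("PDK", init[["PDK"]], "cytosol", c(PDK = 1))
  sp("PDKm", 0, "membrane", c(PDK = 1, PIP = 1))
  sp("AKT", init[["AKT"]], "cytosol", c(AKT = 1))
  sp("AKTm", 0, "membrane", c(AKT = 1, PIP = 1))
  sp("AKTp", 0, "cytosol", c(AKT = 1))
  sp("PTEN", init[["PTEN"]], "cytosol", c(PTEN = 1))
  sp("Ptase", init[["Ptase"]] * ptase_scale, "cytosol", c(Ptase = 1))

  # --- reactions --------------------------------------------------------
  rev2 <- function(a, b, ab, kon, koff, mult = 1) {
    rx(c(a, b), ab, kon, mult)
    rx(ab, c(a, b), koff)
  }
  # ligand binding
  rev2("EGF", "R1", "R1L", "kon_egf", "koff_egf")
  if (has_lap) {
    rev2("EGF", "R1i", "R1Li", "kon_egf", "koff_egf")
    rev2("LAP", "R1", "R1i", "kon_lap", "koff_lap")
    rev2("LAP", "R1L", "R1Li", "kon_lap", "koff_lap")
    rev2("LAP", "R2", "R2i", "kon_lap", "koff_lap")
  }
  # EGFR homodimers (ligand-induced) and mutant basal dimers
  rev2("R1L", "R1L", "D11_0", "kdim11", "kundim")
  rev2("R1", "R1", "D11u_0", "kbasal", "kundim")
  rev2("R1L", "R2", "D12_00", "kdim12", "kundim")
  if (has_lap) {
    rev2("R1L", "R1Li", "D11_1", "kdim11", "kundim", mult = 2)
    rev2("R1Li", "R1Li", "D11_2", "kdim11", "kundim")
    rev2("R1", "R1i", "D11u_1", "kbasal", "kundim", mult = 2)
    rev2("R1i", "R1i", "D11u_2", "kbasal", "kundim")
    rev2("R1Li", "R2", "D12_10", "kdim12", "kundim")
    rev2("R1L", "R2i", "D12_01", "kdim12", "kundim")
    rev2("R1Li", "R2i", "D12_11", "kdim12", "kundim")
  }
  if (has_erbb3) {
    rev2("NRG", "R3", "R3L", "kon_nrg", "koff_nrg")
    rev2("R3L", "R2", "D23_0", "kdim23", "kundim")
    rev2("R3", "R2", "D23c_0", "kconst", "kundim")
    rev2("R3L", "R3L", "D33", "kdim33", "kundim")
    rev2("R3L", "R1", "D13_0", "kdim13", "kundim")
    if (has_lap) {
      rev2("R3L", "R2i", "D23_1", "kdim23", "kundim")
      rev2("R3", "R2i", "D23c_1", "kconst", "kundim")
      rev2("R3L", "R1i", "D13_1", "kdim13", "kundim")
    }
    # receptor trans-phosphorylation of the ErbB3 tail
    rx("D23_0", "D23p_0", "kcat_erbb2")
    rx("D23c_0", "D23cp_0", "kcat_erbb2")
    rx("D33", "D33p", "kcat_erbb3", 2)   # two weak kinases, one per protomer
    rx("D13_0", "D13p_0", "kcat_egfr")
    # dephosphorylation by the generic ErbB phosphatase
    for (dd in list(c("D23p_0", "D23_0"), c("D23cp_0", "D23c_0"),
                    c("D33p", "D33"), c("D13p_0", "D13_0"))) {
      rx(c(dd[1], "Ptase"), c(dd[2], "Ptase"), "kdp_rec")
    }
    # PI3K recruitment on phosphorylated ErbB3
    rev2("D23p_0", "PI3K", "D23p_0P", "kon_pi3k", "koff_pi3k")
    rev2("D23cp_0", "PI3K", "D23cp_0P", "kon_pi3k", "koff_pi3k")
    rev2("D33p", "PI3K", "D33pP", "kon_pi3k", "koff_pi3k")
    rev2("D13p_0", "PI3K", "D13p_0P", "kon_pi3k", "koff_pi3k")
    # internalization of phosphorylated ErbB3 dimers
    rx("D23p_0", "I23", "kint")
    rx("D23cp_0", "I23c", "kint")
    rx("D33p", "I33", "kint")
    rx("D13p_0", "I13", "kint")
  }
  # internalization of EGFR dimers (active receptors leave the surface)
  rx("D11_0", "I11", "kint")
  rx("D11u_0", "I11u", "kint")
  rx("D12_00", "I12", "kint")
  if (has_lap) {
    rx("D11_1", c("I11", "LAP"), "kint")
    rx("D11_2", c("I11", "LAP", "LAP"), "kint")
    rx("D11u_1", c("I11u", "LAP"), "kint")
    rx("D11u_2", c("I11u", "LAP", "LAP"), "kint")
    rx("D12_10", c("I12", "LAP"), "kint")
    rx("D12_01", c("I12", "LAP"), "kint")
    rx("D12_11", c("I12", "LAP", "LAP"), "kint")
  }
  # EGFR C-tail site phosphorylation by catalytically competent dimers;
  # the weight is the number of tails with an active partner kinase.
  tail_catalysts <- list(c("D11_0", 2), c("D11u_0", 2), c("D12_00", 1))
  if (has_lap) {
    tail_catalysts <- c(tail_catalysts,
                        list(c("D11_1", 1), c("D11u_1", 1), c("D12_10", 1)))
  }
  for (tc in tail_catalysts) {
    w <- as.numeric(tc[2])
    rx(c("Y68", tc[1]), c("pY68", tc[1]), "kp68", w)
    rx(c("Y73", tc[1]), c("pY73", tc[1]), "kp73", w)
  }
  rx(c("pY68", "Ptase"), c("Y68", "Ptase"), "kdp_tail")
  rx(c("pY73", "Ptase"), c("Y73", "Ptase"), "kdp_tail")
  # adaptor docking
  rev2("pY68", "Grb2", "pY68G", "kon_grb2", "koff_grb2")
  rev2("pY73", "Shc", "pY73S", "kon_shc", "koff_shc")
  # GAB-1 recruitment by docked Grb2, then PI3K binding
  rx(c("GAB1", "pY68G"), c("GAB1m", "pY68G"), "kgab_on")
  rx("GAB1m", "GAB1", "kgab_off")
  rev2("GAB1m", "PI3K", "GP", "kon_pi3k", "koff_pi3k")
  # PI3K lipid kinase activity of every membrane-recruited PI3K species
  rx(c("PIP2", "GP"), c("PIP3", "GP"), "kpip_gab")
  if (has_erbb3) {
    for (ca in c("D23p_0P", "D23cp_0P", "D33pP", "D13p_0P"))
      rx(c("PIP2", ca), c("PIP3", ca), "kpip")
  }
  rx(c("PIP3", "PTEN"), c("PIP2", "PTEN"), "kpten")
  # AKT activation: PIP3 recruits both AKT and PDK1; membrane PDK1
  # phosphorylates membrane AKT
  rev2("AKT", "PIP3", "AKTm", "kon_akt", "koff_akt")
  rev2("PDK", "PIP3", "PDKm", "kon_pdk", "koff_pdk")
  rx(c("AKTm", "PDKm"), c("AKTp", "PDKm", "PIP3"), "kakt_cat")
  rx("AKTp", "AKT", "kakt_deph")
  # MAPK cascade from both tail arms
  rx(c("RasGDP", "pY68G"), c("RasGTP", "pY68G"), "kras_grb2")
  rx(c("RasGDP", "pY73S"), c("RasGTP", "pY73S"), "kras_shc")
  rx("RasGTP", "RasGDP", "kras_gap")
  rx(c("Raf", "RasGTP"), c("Rafa", "RasGTP"), "kraf_on")
  rx("Rafa", "Raf", "kraf_off")
  rx(c("MEK", "Rafa"), c("MEKp", "Rafa"), "kmek_on")
  rx("MEKp", "MEK", "kmek_deph")
  rx(c("ERK", "MEKp"), c("ERKp", "MEKp"), "kerk_on")
  rx("ERKp", "ERK", "kerk_deph")

  b$finish(params = p,
           metadata = list(mutant = mutant, egf_nM = config$egf_nM %||% 0,
                           nrg_nM = config$nrg_nM %||% 0,
                           lapatinib_nM = config$lapatinib_nM %||% 0,
                           egfr_expression = if (over) "over" else "normal",
                           erbb3_fold = config$erbb3_fold %||% 1,
                           phosphatase_scale = ptase_scale,
                           units = "molecules/cell, minutes",
                           nm_to_molecules = NM_TO_MOLEC))
}

new_model_builder <- function() {
  species <- list(); reactions <- list()
  add_species <- function(name, initial, compartment, composition) {
    if (initial < 0) abort_config("negative initial amount for %s", name)
    species[[name]] <<- list(name = name, initial = initial,
                             compartment = compartment, composition = composition)
  }
  add_reaction <- function(reactants, products, rate_name, multiplier = 1) {
    reactions[[length(reactions) + 1L]] <<- list(
      reactants = table_stoich(reactants), products = table_stoich(products),
      rate_name = rate_name, multiplier = multiplier)
  }
  finish <- function(params, metadata) {
    spdf <- data.frame(
      name = vapply(species, `[[`, character(1), "name"),
      initial = vapply(species, `[[`, numeric(1), "initial"),
      compartment = vapply(species, `[[`, character(1), "compartment"),
      stringsAsFactors = FALSE, row.names = NULL)
    moieties <- unique(unlist(lapply(species, function(s) names(s$composition))))
    comp <- matrix(0, length(moieties), nrow(spdf),
                   dimnames = list(moieties, spdf$name))
    for (s in species) comp[names(s$composition), s$name] <- s$composition
    for (r in reactions) {
      undeclared <- setdiff(c(names(r$reactants), names(r$products)), spdf$name)
      if (length(undeclared))
        abort_config("reaction references undeclared species: %s",
                     paste(undeclared, collapse = ", "))
    }
    structure(list(species = spdf, reactions = reactions, params = params,
                   composition = comp, metadata = metadata),
              class = "ModelSpec")
  }
  list(add_species = add_species, add_reaction = add_reaction, finish = finish)
}

table_stoich <- function(x) {
  tb <- table(x)
  stats::setNames(as.numeric(tb), names(tb))
}

#' @export
print.ModelSpec <- function(x, ...) {
  cat(sprintf("ModelSpec: %d species, %d reactions (%s)\n",
              nrow(x$species), length(x$reactions), x$metadata$units))
  cat(sprintf("  mutant %s, EGF %g nM, NRG %g nM, lapatinib %g nM\n",
              x$metadata$mutant, x$metadata$egf_nM, x$metadata$nrg_nM,
              x$metadata$lapatinib_nM))
  invisible(x)
}

#' Apply a mutant profile to a built model
#'
#' Scales the Y1068/Y1173 tail phosphorylation rate constants, applies the
#' ATP-affinity scale to the EGFR catalytic rates, and sets the
#' ligand-independent activation rate. The WT profile leaves the parameter
#' table unchanged.
#'
#' @param model ModelSpec.
#' @param profile_id packaged profile id or a profile list as returned by
#'   [mutant_profile()].
#' @return ModelSpec with updated parameters and metadata.
#' @export
apply_mutant <- function(model, profile_id) {
  prof <- if (is.list(profile_id)) profile_id else mutant_profile(profile_id)
  p <- model$params
  atp <- prof$atp_scale %||% 1
  p[["kp68"]] <- p[["kp_tail"]] * prof$y1068_scale * atp
  p[["kp73"]] <- p[["kp_tail"]] * prof$y1173_scale * atp
  p[["kcat_egfr"]] <- p[["kcat"]] * atp
  p[["kbasal"]] <- prof$basal_rate
  model$params <- p
  model$metadata$mutant <- if (is.list(profile_id)) "custom" else profile_id
  model
}

#' Mass-action derivative evaluator
#'
#' Compiles the reaction list into an efficient closure: each reaction
#' rate is its rate constant times the product of reactant amounts (with
#' stoichiometric powers); species derivatives are the stoichiometry-
#' weighted sums of rates.
#'
#' @param model ModelSpec.
#' @return function(t, y, parms) suitable for [deSolve::lsoda()]; also
#'   callable directly for a derivative vector.
#' @export
mass_action_rhs <- function(model) {
  spn <- model$species$name
  ns <- length(spn)
  nr <- length(model$reactions)
  k <- numeric(nr); i1 <- integer(nr); i2 <- integer(nr); squared <- logical(nr)
  S <- matrix(0, ns, nr, dimnames = list(spn, NULL))
  for (j in seq_len(nr)) {
    r <- model$reactions[[j]]
    k[j] <- model$params[[r$rate_name]] * r$multiplier
    ridx <- match(names(r$reactants), spn)
    sto <- r$reactants
    if (sum(sto) > 2) abort_config("mass-action reactions are at most bimolecular")
    if (length(ridx) == 1 && sto[1] == 2) {
      i1[j] <- ridx; i2[j] <- ridx; squared[j] <- TRUE
    } else if (length(ridx) == 2) {
      i1[j] <- ridx[1]; i2[j] <- ridx[2]
    } else {
      i1[j] <- ridx[1]; i2[j] <- 0L
    }
    S[ridx, j] <- S[ridx, j] - sto
    pidx <- match(names(r$products), spn)
    S[pidx, j] <- S[pidx, j] + r$products
  }
  has2 <- i2 > 0L
  function(t, y, parms = NULL) {
    if (any(y < -1e-6)) abort_input("negative state passed to mass-action RHS")
    y <- pmax(y, 0)
    rates <- k * y[i1]
    rates[has2] <- rates[has2] * y[i2[has2]]
    list(as.numeric(S %*% rates))
  }
}

#' Conserved moiety totals of a state
#'
#' @param model ModelSpec.
#' @param state named or ordered numeric state vector.
#' @return named totals (one per receptor, ligand, adaptor moiety).
#' @export
conserved_totals <- function(model, state) {
  as.numeric(model$composition %*% state) -> tot
  stats::setNames(tot, rownames(model$composition))
}

#' Integrate the signaling model
#'
#' Stiff-capable integration (lsoda). Conserved receptor/adaptor totals
#' are checked against the initial state; drift beyond 1e-6 relative is an
#' integration error.
#'
#' @param model ModelSpec.
#' @param t_end end time, minutes (default 60).
#' @param dt reporting interval, minutes.
#' @param rtol,atol solver tolerances.
#' @return object of class `SimulationResult`: `times`, `state` (time x
#'   species matrix, clipped at 0 for reporting), `model`, `diagnostics`.
#' @export
simulate_model <- function(model, t_end = 60, dt = 0.25, rtol = 1e-8, atol = 1e-12) {
  if (t_end <= 0) abort_usage("t_end must be positive")
  rhs <- mass_action_rhs(model)
  y0 <- stats::setNames(model$species$initial, model$species$name)
  times <- seq(0, t_end, by = dt)
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  if (attr(out, "istate")[1] < 0)
    abort_integration("ODE solver failed (istate %d)", attr(out, "istate")[1])
  state <- out[, -1, drop = FALSE]
  min_amount <- min(state)
  drift <- if (nrow(model$composition) == 0) 0 else {
    tot0 <- conserved_totals(model, state[1, ])
    totT <- conserved_totals(model, state[nrow(state), ])
    max(abs(totT - tot0) / pmax(abs(tot0), 1))
  }
  if (drift > 1e-6)
    abort_integration("conserved totals drifted by %.2e relative", drift)
  state[state < 0] <- 0
  structure(list(times = out[, 1], state = state, model = model,
                 diagnostics = list(drift = drift, min_amount = min_amount)),
            class = "SimulationResult")
}

#' Scalar readout from a simulation
#'
#' @param result SimulationResult.
#' @param species species name (e.g. "ERKp", "AKTp").
#' @param metric `"peak"`, `"integral"` (trapezoid on the solver grid) or
#'   `"value_at"`.
#' @param t time for `value_at` (linear interpolation).
#' @return scalar.
#' @export
output_metric <- function(result, species, metric = c("peak", "integral", "value_at"),
                          t = NULL) {
  metric <- match.arg(metric)
  if (!species %in% colnames(result$state))
    abort_lookup("unknown species '%s'", species)
  y <- result$state[, species]
  tt <- result$times
  switch(metric,
         peak = max(y),
         integral = sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2),
         value_at = {
           if (is.null(t)) abort_usage("value_at needs t")
           stats::approx(tt, y, xout = t)$y
         })
}
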