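---
title: "Multiscale analysis of ErbB kinase activation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale analysis of ErbB kinase activation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

The ErbB/EGFR/HER receptor tyrosine kinases switch between an inactive and
an active kinase-domain conformation, and clinically identified somatic
mutations bias that switch. `erbbscale` implements two layers of analysis
around this biology:

* **molecular layer** — statistics over kinase-domain coordinate
  trajectories: superposition/RMSD/RMSF, principal component analysis of
  C$\alpha$ fluctuations, per-frame salt-bridge and hydrogen-bond
  detection with survival fractions and persistent-network comparison,
  and a water-density-fluctuation hydrophobicity measure paired with
  solvent accessible surface area (SASA) and a quadrant classification;
* **cellular layer** — a mass-action ODE model of ErbB signaling with
  site-resolved EGFR C-tail phosphorylation, oncogenic mutant profiles,
  the inhibitor lapatinib, weak ErbB3 catalysis, and local/global
  parameter sensitivity analysis.

A static knowledge base (kinase subdomain maps, hydrophobic region
residue lists, a clinical mutation catalog, and the curated persistent
hydrophilic interaction table for the ErbB monomers) connects the two
layers, and a synthetic-data module generates every input class with
known ground truth. Running molecular dynamics itself, homology modeling,
alchemical free-energy calculations and live database queries are out of
scope; the package consumes trajectories and curated tables.

# Trajectory statistics

## Superposition and PCA

All fluctuation statistics remove rigid-body motion first. `superpose()`
is the closed-form least-squares (Kabsch) fit; trajectory operations use
a two-pass mean-structure superposition: frames are fitted to the first
frame, averaged, then refitted to that mean. With a mean reference the
eigenvalue sum of the coordinate covariance equals the total positional
variance, which the tests assert to `1e-6` relative.

`pca_fluctuations()` diagonalises the $3N \times 3N$ covariance of the
selected coordinates. Two conventions are fixed deliberately:

* **population normalisation** (divide by the number of frames, not
  $n-1$) — the same convention the hydrophobicity statistic uses for its
  moments, so the two modules cannot disagree on what "variance" means;
* **unweighted C$\alpha$ selection** by default — mass weighting and
  hydrogen handling are irrelevant at C$\alpha$ resolution, and
  free-floating terminal tails are *kept*: tail-dominated leading modes
  are expected behaviour of these systems, not an artifact, and can be
  masked explicitly via the `selection` argument.

Because superposition projects out the six rigid-body modes, a planted
displacement pattern is recoverable only up to its non-rigid component;
the planted-mode acceptance test therefore measures subspace overlap
against the rigid-projected patterns. This is a property of any
superposed-fluctuation analysis, not of this implementation.

## Interaction networks

Salt bridges are charged-heavy-atom contacts (Lys NZ, Arg NE/NH1/NH2,
His ND1/NE2 against Asp OD1/OD2, Glu OE1/OE2) within 4.0 Å; hydrogen
bonds are donor–acceptor heavy-atom pairs within 3.5 Å with a
donor–hydrogen–acceptor angle of at least 120°, falling back to a
90° acceptor–donor–antecedent proxy when hydrogens are absent. The
source study reports bonds but not geometric criteria, so these are the
common literature conventions, exposed through `contact_criteria()`
rather than hidden.

Interactions are residue-level: any qualifying atom pair marks the
residue pair present in that frame. The *survival fraction* is the
fraction of frames a pair is present; `persistent_network()` keeps pairs
at or above a threshold, defaulting to 0.6 — the curated ErbB table
counts a bond that has decayed to roughly 70% survival in the dimer
context as still present, so the bar must sit below 0.7. A pair is typed
salt-bridge when the salt-bridge detector fires in at least half of its
present frames; the same rule decides ambiguous cases such as the
catalytic-loop pair that is a salt bridge in EGFR/ErbB4 but an H-bond in
ErbB2 — the packaged table stores the printed typing, while the
geometric rule governs anything computed from coordinates.

`conserved_interactions()` intersects homology rows of the curated table
across kinases. By default it is *state-characteristic*: a row present
in every requested kinase at the requested state, and absent from the
opposite state for those kinases. This reproduces exactly the six
interactions that define the active-state network across
EGFR/ErbB2/ErbB4; the plain intersection (available via
`state_specific = FALSE`) additionally picks up one bond that is present
in both conformations and therefore distinguishes neither.

## Hydrophobicity and SASA

The hydrophobicity of a protein sub-region is measured through water
density fluctuations: $\chi = \mathrm{Vol}_N \,(\langle N^2\rangle -
\langle N\rangle^2)/\langle N\rangle^2$, where $N$ counts water oxygens
inside the observation volume. $\chi$ is normalised by a bulk reference
so 1 marks a neutral region; values above 1 (enhanced fluctuations)
signal hydrophobicity, below 1 hydrophilicity. The observation volume is
a union of 5.5 Å spheres centred on the region's heavy atoms, minus
protein-interior points under van der Waals spheres, measured on a
0.25 Å grid; the source study never defines its observation volume, so
every one of these parameters is an exposed argument. The bulk reference
is the mean raw $\chi$ over seeded random congruent placements of the
same probe away from the protein; whether the volume is held fixed
across systems or recomputed is likewise left to the caller
(`build_probe_volume()` per system, or one probe reused).

SASA uses the classic sphere-point (Shrake–Rupley) construction with a
1.4 Å probe and 960 deterministic golden-spiral points per atom,
validated against the closed form $4\pi(r + 1.4)^2$ for an isolated
atom. Quadrant classification of (SASA, $\chi_{norm}$) points fixes the
$\chi$ split at the neutral value 1; the SASA split is data-driven
(median of the analysed point set) because no absolute split is defined
for it. Ties go to the lower quadrant index, so a double-boundary point
is quadrant I.

# The signaling model

## Structure

The model is pure mass action (at most bimolecular reactions), in
molecules/cell and minutes, with ligand doses converted at 6000
molecules per nM per cell. The receptor layer covers EGF binding to
EGFR, NRG-1β binding to ErbB3, a ligandless ErbB2, homo- and
heterodimerization (EGFR:EGFR, EGFR:ErbB2, ErbB2:ErbB3, ErbB3:ErbB3 and
a weak EGFR:ErbB3 route), slow constitutive ErbB2:ErbB3 dimerization,
trans-phosphorylation, a generic ErbB phosphatase, and internalization
of phosphorylated dimers. ErbB4 is omitted: its signaling is weak or
absent in the cancer cell contexts the model addresses. Receptor
trafficking beyond internalization/degradation is not modelled.

Phosphorylation is strictly *trans*: each protomer's kinase acts on its
partner. ErbB3 is a weak kinase whose catalytic rate is the canonical
rate divided by 1000 (`kcat_erbb3`), so NRG-driven ErbB3 homodimers
carry a small but real phosphorylation flux — the molecular basis of the
resistance scenario. Lapatinib binds EGFR and ErbB2 monomers; bound
receptors still bind ligand and dimerize but contribute zero catalytic
rate, so a lapatinib-bound ErbB2 in an ErbB2:ErbB3 dimer silences that
dimer while sequestering its ErbB3.

The EGFR C-terminal tail resolves two docking sites as explicit species
pools: Y1068 (Grb2, then GAB-1, then PI3K) and Y1173 (Shc). Both arms
drive Ras→Raf→MEK→ERK; the GAB-1 arm and phosphorylated ErbB3 recruit
PI3K, which converts PIP2 to PIP3 against PTEN. AKT activation requires
PIP3 binding of both AKT and PDK1 (both have PH domains), which gives
the pAKT response an effective Hill coefficient near 2 — the source of
the threshold-like behaviour the resistance scenario needs. The tail
pools are a deliberate approximation: sites are tracked in parallel to
the dimer species rather than enumerated per dimer, which keeps the
state space near 70 species while preserving site-specific kinetics;
site totals are conserved separately from receptor totals, and
internalization acts on dimers (the catalysts), not on the pools.

Every species carries a composition vector over conserved moieties
(receptors, ligands, drug, adaptors, lipid, site pools), so conservation
is checkable as a left-null-space identity of the stoichiometry and is
asserted after every integration (drift < `1e-6` relative at
`rtol = 1e-8`, `atol = 1e-12`).

## Mutant profiles

Mutant profiles scale the two tail-site phosphorylation rate constants,
apply an ATP-affinity factor to the EGFR catalytic rates, and set a
ligand-independent (basal) dimerization rate; the WT profile is the
identity. L834R carries `y1068_scale = 0.80`, `y1173_scale = 0.055`: the
mutation redistributes site preference toward Y1068, which is what makes
ERK output collapse five-fold while AKT output drops only ~15%. The
deletion mutant keeps WT site kinetics but a ten-fold larger basal rate,
which is what sustains its late-time signal after ligand-driven
signaling has internalized. The L834R/T766M resistance double mutant
multiplies both site rates by exactly 100. The readout for "activation"
is the peak of pERK or pAKT over 0–60 minutes; peak was chosen over
integrated or steady-state readouts because the transient maximum is the
conventional comparison point for these pathways, and `output_metric()`
provides the other two for anyone who prefers them.

## Calibration

No rate constants are printed in the source literature for this exact
network, so the packaged constants are the package's own, calibrated
(scripts/calibrate.R) to the headline behaviours: the L834R fold-changes
(5-fold pERK, 15% pAKT), the lapatinib/ErbB3 recovery points (~60% of
the no-inhibitor control at 25 nM NRG-1β with 2× surface ErbB3, ~100% at
100 nM, a small positive residual at 1×), and the sensitivity structure
(below). Three structural choices make these simultaneously reachable:

1. the ErbB3-homodimer drive stays quadratic in ErbB3 and in NRG
   occupancy (low dimerized fraction, linear PI3K capture), so doubling
   ErbB3 quadruples the drive and raising NRG from 25 to 100 nM
   (Kd ≈ 190 nM) multiplies it ~9-fold;
2. the AKT step saturates (PIP3-binding of AKT and PDK1 plus pool
   depletion), so the 2×/100 nM scenario reaches the control plateau
   while the 1× residual stays small;
3. the no-inhibitor control is kept off deep saturation by weak
   ErbB2:ErbB3 and EGFR:ErbB3 heterodimerization, so its sensitivities
   are non-trivial.

Under 25 nM NRG-1β the calibrated model gives positive pAKT
coefficients ordered ErbB3 > ErbB2 > NRG ≫ EGFR with PTEN and the ErbB
phosphatase negative; adding saturating lapatinib raises the ErbB3 and
NRG-1β coefficients several-fold, drives EGFR/ErbB2 toward zero (they
are sequestered), and deepens the negative phosphatase coefficient. The
global screen (log-uniform Latin hypercube, partial rank correlation)
under joint EGF+NRG stimulation ranks PI3K, MEK and the AKT-branch pools
among the top components. These statements are exactly what the
acceptance tests assert; nothing beyond them is claimed.

## Sensitivity machinery

`local_sensitivity()` returns dimensionless logarithmic coefficients
$S = \partial \log y / \partial \log p$ by central differences (default
5% step). `global_sensitivity()` samples log-uniformly over ranges
(default 0.2×–5× base) with `lhs::randomLHS()` and computes partial rank
correlation coefficients; degenerate ranges are reported as coefficient
0 with a warning. Both accept rate constants, species initials, and the
receptor aliases EGFR/ErbB2/ErbB3. `fit_rate_constants()` is a seeded
multi-start box-bounded least-squares fit over up to five log-scaled
parameters with a flat-objective identifiability probe.

# Synthetic data

Every generator is a pure function of (recipe, seed) and returns its
ground truth:

* `make_toy_kinase()` — a poly-alanine chain with helix/loop labels and
  a planted Lys/Glu salt bridge; side-chain geometry is schematic (the
  detectors only need the planted contact distances and antecedent
  atoms), not stereochemically correct;
* `make_planted_mode_trajectory()` — sinusoidal orthogonal displacement
  patterns plus isotropic Gaussian noise;
* `make_water_box()` — ideal-gas water frames: per-frame counts are
  Poisson (neutral), binomial over a fixed pool (suppressed,
  variance/mean = 0.5) or a two-state Poisson mixture (enhanced);
  positions are resampled independently every frame because the $\chi$
  statistic depends only on count marginals, which makes standard-error
  formulas exact for the tests. Default density 0.0334 Å⁻³ (liquid
  water). Waters beyond the per-frame count are parked far outside the
  box so the topology's atom count is constant;
* `make_planted_interaction_traj()` — Bernoulli contact states at target
  survival fractions realized by swinging a Lys side chain;
* `make_signaling_dataset()` — model time courses with multiplicative
  lognormal noise.

What passing tests on these fixtures shows — and does not show: the
generators emulate the *statistical structure* of trajectory and
signaling data (planted low-frequency modes, count-fluctuation regimes,
on/off contact kinetics, multiplicative observation noise), not protein
energetics, water structure, correlated dynamics or real measurement
error. Green tests certify that the estimators recover known ground
truth under their stated assumptions; they do not certify force-field
realism, and the MD-derived numbers of the original study (absolute
SASA levels, eigenmode variance fractions, per-pair survival values)
require the original trajectories.

# Problem sizes and numerical choices

The default test and acceptance runs use: 2000-frame water boxes at
40 Å for the bulk-neutrality check (three-sphere probe, 50 bulk
placements), 200–800-frame planted-mode trajectories on 20–30-residue
toys, 200–500-frame planted networks, 0–60-minute signaling simulations
on a 0.25–1-minute grid, and a 500-sample global screen over 14
parameters. These sizes put every statistical assertion at least three
standard errors from its threshold while keeping a full run on one CPU
comfortable. Degenerate inputs are errors, not guesses: empty
selections, unresolvable residue pairs, zero mean water counts,
non-positive bulk references, collinear superposition selections and
impossible probe placements all raise classed conditions
(`erbb_usage_error`, `erbb_lookup_error`, `erbb_statistics_error`, …)
that tests assert by class.

# Known limitations

* The XTC trajectory dialect is recognised but not implemented (no
  installed reader; DCD and multi-model PDB cover all uses here).
* Numbering offsets are packaged for EGFR only; other ErbB members
  raise lookup errors unless user-configured — inventing offsets would
  be worse than refusing.
* The hydrophobic-core residue lists and all non-EGFR spine lists are
  provisional (flagged in the data file): they are placed by
  family-alignment offsets, not by structure inspection.
* Tail-site pools decouple site phosphorylation from dimer identity;
  analyses that need per-dimer tail states (e.g. processive
  phosphorylation) are outside this model.
* The ErbB2 αC-β4 "region" packages the interacting hydrophobic patch
  (loop plus A-loop residues) rather than a sequential interval.
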