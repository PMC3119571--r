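# Default parameter set for the ErbB signaling model.
# Units: molecules/cell and minutes; bimolecular constants are per
# (molecule x minute); ligand doses convert at 6000 molecules per nM.
# Values are the package's own calibrated set (see scripts/calibrate.R for
# the procedure and targets); the network topology follows the published
# ErbB models it is built on, but no rate constants are taken from the
# literature.
params:
  kon_egf: 3.0e-05      # EGF-EGFR association (Kd ~ 1.7 nM)
  koff_egf: 0.3
  kon_nrg: 1.0e-05      # NRG-1beta-ErbB3 association (Kd ~ 190 nM)
  koff_nrg: 11.56
  kon_lap: 1.0e-04      # lapatinib binding to EGFR/ErbB2
  koff_lap: 0.01
  kdim11: 1.0e-05       # ligand-bound EGFR homodimerization
  kdim12: 1.0e-05       # EGFR-ErbB2 heterodimerization (EGF-driven)
  kdim23: 1.0e-08       # ErbB2-ErbB3 (NRG-bound) heterodimerization
  kdim33: 1.65e-05      # ErbB3 homodimerization (NRG-bound)
  kdim13: 2.0e-09       # weak EGFR-ErbB3 route under NRG
  kconst: 1.0e-08       # constitutive ErbB2-ErbB3 dimerization
  kundim: 0.1
  kcat: 5.0             # canonical receiver-kinase catalytic rate
  kp_tail: 1.4e-05      # C-tail site phosphorylation per active dimer
  kdp_rec: 1.0e-06      # ErbB phosphatase on phospho-receptor dimers
  kdp_tail: 4.0e-05     # ErbB phosphatase on Y1068/Y1173 site pools
  kint: 0.05            # internalization of active dimers
  kon_grb2: 1.0e-05
  koff_grb2: 1.0
  kon_shc: 1.0e-05
  koff_shc: 1.0
  kgab_on: 1.0e-05
  kgab_off: 1.0
  kon_pi3k: 1.0e-05
  koff_pi3k: 2.0
  kpip: 1.0e-04         # PIP2 -> PIP3 per receptor-bound PI3K
  kpip_gab: 5.708e-06   # PIP2 -> PIP3 per GAB-1-bound PI3K
  kpten: 2.991e-06      # PTEN PIP3 phosphatase
  kon_akt: 2.612e-04
  koff_akt: 1.0
  kon_pdk: 2.612e-04
  koff_pdk: 1.0
  kakt_cat: 1.0e-05     # membrane PDK1 phosphorylates membrane AKT
  kakt_deph: 0.5
  kras_grb2: 3.881e-07  # Ras exchange driven by the pY1068-Grb2 arm
  kras_shc: 5.443e-06   # Ras exchange driven by the pY1173-Shc arm
  kras_gap: 0.5
  kraf_on: 5.0e-06
  kraf_off: 0.2
  kmek_on: 1.0e-05
  kmek_deph: 0.2
  kerk_on: 1.0e-06
  kerk_deph: 0.2
initials:
  EGFR: 1.0e+05         # normal expression; "over-expressed" = 10x
  ErbB2: 1.0e+05
  ErbB3: 2.0e+04
  Grb2: 1.0e+05
  Shc: 1.0e+05
  GAB1: 5.0e+04
  PI3K: 5.0e+04
  Ras: 1.0e+05
  Raf: 1.0e+04
  MEK: 1.0e+05
  ERK: 2.0e+05
  PIP2: 5.0e+05
  PDK: 1.0e+05
  AKT: 1.0e+05
  PTEN: 5.0e+04
  Ptase: 5.0e+04
profiles:
  WT:
    y1068_scale: 1.0
    y1173_scale: 1.0
    atp_scale: 1.0
    basal_rate: 0.0
  L834R:
    y1068_scale: 0.8009
    y1173_scale: 0.05486
    atp_scale: 1.0
    basal_rate: 2.0e-09
  del723-729insS:
    y1068_scale: 1.0
    y1173_scale: 1.0
    atp_scale: 1.0
    basal_rate: 2.0e-08
  L834R/T766M:
    y1068_scale: 100.0
    y1173_scale: 100.0
    atp_scale: 1.0
    basal_rate: 2.0e-09
units:
  amount: molecules/cell
  time: minutes
  ligand_dose: nM (6000 molecules per nM)
scenario_defaults:
  egf_nM: 8
  nrg_nM: 25
  lapatinib_saturating_nM: 10000
  readout_window_min: 60
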