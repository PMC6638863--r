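# Per-PFT allometric and radiative constants for temperate hardwood PFTs.
#
# Allometric coefficients (SLA, leaf-biomass, WAI and height curves) are
# editable placeholders calibrated so that (a) the canonical height order of
# the three PFTs at DBH 25 cm is early > mid > late, reversing to
# mid > late > early when early DBH drops to 20 cm, and (b) biomass-derived
# LAI at DBH 25 cm matches ~6 at the canonical single-cohort stem densities.
#
# Units: sla m2 kg-1; bleaf_b1 kg cm^-bleaf_b2; wai allometry gives m2 m-2
# per stem density; href, height_b1 m; height_b2 cm-1 (negative: saturating).
# Radiative defaults are the prior medians of the bundled parameter table.
early:
  pft_label: early
  sla: 30.0
  bleaf_b1: 0.01552
  bleaf_b2: 1.56
  wai_b1: 0.0096
  wai_b2: 2.0
  href: 1.3
  height_b1: 35.0
  height_b2: -0.040
  clumping: 0.69
  orientation: 0.0
  leaf_r_par: 0.0791
  leaf_t_par: 0.0541
  leaf_r_nir: 0.2618
  leaf_t_nir: 0.2891
  wood_r_par: 0.15
  wood_t_par: 0.003
  wood_r_nir: 0.30
  wood_t_nir: 0.003
mid:
  pft_label: mid
  sla: 25.0
  bleaf_b1: 0.02699
  bleaf_b2: 1.56
  wai_b1: 0.0096
  wai_b2: 2.0
  href: 1.3
  height_b1: 30.0
  height_b2: -0.045
  clumping: 0.69
  orientation: 0.0
  leaf_r_par: 0.0791
  leaf_t_par: 0.0541
  leaf_r_nir: 0.2618
  leaf_t_nir: 0.2891
  wood_r_par: 0.15
  wood_t_par: 0.003
  wood_r_nir: 0.30
  wood_t_nir: 0.003
late:
  pft_label: late
  sla: 20.0
  bleaf_b1: 0.02904
  bleaf_b2: 1.56
  wai_b1: 0.0096
  wai_b2: 2.0
  href: 1.3
  height_b1: 32.0
  height_b2: -0.038
  clumping: 0.69
  orientation: 0.0
  leaf_r_par: 0.0791
  leaf_t_par: 0.0541
  leaf_r_nir: 0.2618
  leaf_t_nir: 0.2891
  wood_r_par: 0.15
  wood_t_par: 0.003
  wood_r_nir: 0.30
  wood_t_nir: 0.003
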