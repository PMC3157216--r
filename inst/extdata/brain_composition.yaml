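# Brain compartment composition: water fraction of wet weight, total
# protein fraction of dry weight, myelin basic protein per g total protein,
# MBP molecular weight (major human isoform), and the mass fraction each
# compartment contributes to total brain mass.
white_matter:
  water_fraction: 0.72
  protein_dry_fraction: 0.39
  target_mg_per_g_protein: 172
  target_mw: 18500
gray_matter:
  water_fraction: 0.82
  protein_dry_fraction: 0.553
  target_mg_per_g_protein: 25
  target_mw: 18500
lesion:
  water_fraction: 0.76
  protein_dry_fraction: 0.317
  target_mg_per_g_protein: 87.8
  target_mw: 18500
mass_fraction:
  white_matter: 0.42
  gray_matter: 0.56
  lesion: 0.02
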