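# Decay emission inventories for the Cs-bearing particle source.
# Compiled from standard decay-scheme compilations (ICRP-107-like values);
# energies in keV, intensities/yields in emissions per parent decay.
# Emissions with per-decay yield < 0.01 are omitted (documented cutoff).
# Cs-137 folds its Ba-137m daughter (secular equilibrium): the 661.66 keV
# gamma, Ba K X-rays and the K/L conversion electrons are scaled by the
# 0.944 branching to the isomer.
version: 1
nuclides:
  Cs137:
    name: Cs-137
    daughter_Z: 56
    includes_daughter: true
    beta_branches:
      - endpoint_keV: 511.6
        intensity: 0.947
      - endpoint_keV: 1175.6
        intensity: 0.053
    lines:
      - {kind: gamma, energy_keV: 661.66, yield: 0.851}
      - {kind: gamma, energy_keV: 32.1, yield: 0.0570}
      - {kind: gamma, energy_keV: 36.4, yield: 0.0132}
      - {kind: electron, energy_keV: 624.2, yield: 0.0779}
      - {kind: electron, energy_keV: 655.7, yield: 0.0111}
  Cs134:
    name: Cs-134
    daughter_Z: 56
    includes_daughter: false
    beta_branches:
      - endpoint_keV: 88.6
        intensity: 0.273
      - endpoint_keV: 415.4
        intensity: 0.025
      - endpoint_keV: 658.1
        intensity: 0.701
    lines:
      - {kind: gamma, energy_keV: 475.37, yield: 0.0148}
      - {kind: gamma, energy_keV: 563.25, yield: 0.0834}
      - {kind: gamma, energy_keV: 569.33, yield: 0.1537}
      - {kind: gamma, energy_keV: 604.72, yield: 0.9762}
      - {kind: gamma, energy_keV: 795.86, yield: 0.8546}
      - {kind: gamma, energy_keV: 801.95, yield: 0.0869}
      - {kind: gamma, energy_keV: 1167.97, yield: 0.0179}
      - {kind: gamma, energy_keV: 1365.19, yield: 0.0301}
source:
  activities_Bq:
    Cs137: 469.2
    Cs134: 38.5
  reference_note: "activities as of 2011-03-11"
  total_activity_override: null
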