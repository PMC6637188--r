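# Material properties for the particle/capillary/dish scene.
# density in g/cm^3; stopping_ratio is the per-material stopping-power ratio
# applied on top of density scaling when converting electron path lengths to
# water-equivalent lengths (1.0 = pure density scaling).
# buildup: Berger-form buildup factor B(mu*r) = 1 + a * mu*r * exp(b * mu*r),
# applied over the water portion of a photon path (near-unity at mm depths).
version: 1
materials:
  water:
    density: 1.0
    stopping_ratio: 1.0
  air:
    density: 0.001205
    stopping_ratio: 1.0
  SiO2:
    density: 2.2
    stopping_ratio: 1.0
  glass:
    density: 2.5
    stopping_ratio: 1.0
buildup:
  water:
    a: 1.05
    b: 0.03
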