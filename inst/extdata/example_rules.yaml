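# Example per-geometry rule profile. Any subset of the default
# configuration may be overridden; unlisted values keep their defaults.
# Thresholds are in the raw Dirichlet-data units of the distance catalog,
# angles in degrees (endo, epi).
flags:
  cs_ic: true
  pm: true
tauLayer: 0.5
tau:
  mv: 0.85
  laa: -0.95
pm:
  tk: 0.15
  rg: 0.15
  end: 0.9
  n: 4
angles:
  MV: [-60, -60]
  LAA: [-30, 30]
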