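{
  "_comment": "Ring systems used for center-of-geometry stacking, keyed by residue name. Purines carry two rings (the minimum-ring rule picks the closer COG); pyrimidines one six-membered ring; arginine contributes the planar guanidinium group for pi-cation stacking. Editable: evaluation resolves atom names against this table at run time.",
  "A": [
    {"label": "imidazole_ring", "atoms": ["C4", "C5", "N7", "C8", "N9"]},
    {"label": "pyrimidine_ring", "atoms": ["N1", "C2", "N3", "C4", "C5", "C6"]}
  ],
  "G": [
    {"label": "imidazole_ring", "atoms": ["C4", "C5", "N7", "C8", "N9"]},
    {"label": "pyrimidine_ring", "atoms": ["N1", "C2", "N3", "C4", "C5", "C6"]}
  ],
  "C": [
    {"label": "pyrimidine_ring", "atoms": ["N1", "C2", "N3", "C4", "C5", "C6"]}
  ],
  "U": [
    {"label": "pyrimidine_ring", "atoms": ["N1", "C2", "N3", "C4", "C5", "C6"]}
  ],
  "ARG": [
    {"label": "guanidinium", "atoms": ["NE", "CZ", "NH1", "NH2"]}
  ]
}
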