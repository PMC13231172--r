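{
  "_comment": "Donor/acceptor catalogue for geometric H-bond calling, keyed by residue name. Donors list the heavy atom and its explicit hydrogens; acceptors are heavy atoms. Covers the Watson-Crick and Hoogsteen edges of the RNA bases, the ribose 2'-hydroxyl (donor and acceptor, as in cpptraj-style default perception; entries are skipped when the atoms are absent) and the arginine guanidinium edge. This is a documented reconstruction of cpptraj-style default perception, user-overridable per catalogue.",
  "G": {
    "donors": [
      {
        "heavy": "N1",
        "hydrogens": [
          "H1"
        ]
      },
      {
        "heavy": "N2",
        "hydrogens": [
          "H21",
          "H22"
        ]
      },
      {
        "heavy": "O2'",
        "hydrogens": [
          "HO2'"
        ]
      }
    ],
    "acceptors": [
      "O6",
      "N7",
      "N3",
      "O2'"
    ]
  },
  "A": {
    "donors": [
      {
        "heavy": "N6",
        "hydrogens": [
          "H61",
          "H62"
        ]
      },
      {
        "heavy": "O2'",
        "hydrogens": [
          "HO2'"
        ]
      }
    ],
    "acceptors": [
      "N1",
      "N7",
      "N3",
      "O2'"
    ]
  },
  "C": {
    "donors": [
      {
        "heavy": "N4",
        "hydrogens": [
          "H41",
          "H42"
        ]
      },
      {
        "heavy": "O2'",
        "hydrogens": [
          "HO2'"
        ]
      }
    ],
    "acceptors": [
      "O2",
      "N3",
      "O2'"
    ]
  },
  "U": {
    "donors": [
      {
        "heavy": "N3",
        "hydrogens": [
          "H3"
        ]
      },
      {
        "heavy": "O2'",
        "hydrogens": [
          "HO2'"
        ]
      }
    ],
    "acceptors": [
      "O2",
      "O4",
      "O2'"
    ]
  },
  "ARG": {
    "donors": [
      {
        "heavy": "NE",
        "hydrogens": [
          "HE"
        ]
      },
      {
        "heavy": "NH1",
        "hydrogens": [
          "HH11",
          "HH12"
        ]
      },
      {
        "heavy": "NH2",
        "hydrogens": [
          "HH21",
          "HH22"
        ]
      }
    ],
    "acceptors": []
  }
}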