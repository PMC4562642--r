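{
  "_provenance": "synthetic, artifact-derived reference calibration; qualitative structure only (the original fitted coefficients were never published)",
  "V0": 1,
  "seed_density": 1e+05,
  "groups": [
    {
      "id": "HSC",
      "members": ["CD34+CD38-CD90+CD45RA-"],
      "w": 0.6,
      "is_cd34": true,
      "growth": {"kind": "exponential", "a": 0.3, "b": -0.006, "domain": [0, 600]}
    },
    {
      "id": "MPP",
      "members": ["CD34+CD38-CD90-CD45RA-"],
      "w": 0.7,
      "is_cd34": true,
      "growth": {"kind": "exponential", "a": 0.38, "b": -0.005, "domain": [0, 600]}
    },
    {
      "id": "CMP_GMP",
      "members": ["CD34+CD38+CD135+"],
      "w": 0.9,
      "is_cd34": true,
      "growth": {"kind": "spline", "knots_conc": [0, 50, 85, 150, 300, 600], "knots_rate": [0.3, 0.4, 0.43, 0.36, 0.22, 0.1], "domain": [0, 600]}
    },
    {
      "id": "MEP",
      "members": ["CD34+CD38+CD135-CD41+"],
      "w": 1.1,
      "is_cd34": true,
      "growth": {"kind": "spline", "knots_conc": [0, 50, 85, 150, 300, 600], "knots_rate": [0.26, 0.36, 0.4, 0.33, 0.2, 0.09], "domain": [0, 600]}
    },
    {
      "id": "EarlyMature",
      "members": ["CD34-CD33+", "CD34-CD71+"],
      "w": 1.2,
      "is_cd34": false,
      "growth": {"kind": "spline", "knots_conc": [0, 100, 300, 600], "knots_rate": [0.28, 0.25, 0.21, 0.18], "domain": [0, 600]}
    },
    {
      "id": "NK",
      "members": ["CD34-CD56+"],
      "w": 1.0,
      "is_cd34": false,
      "growth": {"kind": "spline", "knots_conc": [0, 100, 300, 600], "knots_rate": [0.1, 0.12, 0.15, 0.16], "domain": [0, 600]}
    },
    {
      "id": "T",
      "members": ["CD34-CD3+"],
      "w": 0.9,
      "is_cd34": false,
      "growth": {"kind": "spline", "knots_conc": [0, 100, 300, 600], "knots_rate": [0.08, 0.1, 0.13, 0.15], "domain": [0, 600]}
    },
    {
      "id": "ERY",
      "members": ["CD34-GlyA+"],
      "w": 1.4,
      "is_cd34": false,
      "growth": {"kind": "spline", "knots_conc": [0, 100, 300, 600], "knots_rate": [0.2, 0.22, 0.25, 0.25], "domain": [0, 600]}
    },
    {
      "id": "NEUT",
      "members": ["CD34-CD15+CD66b+"],
      "w": 1.3,
      "is_cd34": false,
      "growth": {"kind": "spline", "knots_conc": [0, 100, 300, 600], "knots_rate": [0.24, 0.26, 0.29, 0.3], "domain": [0, 600]}
    }
  ],
  "secretion": {"kind": "constant_per_cell", "s": 0.0004}
}
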