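{
  "comment": "Synthetic default thresholds (Angstrom) along the pore axis; not fitted to any experimental or simulation data set. Boundaries: INTRA/S6, S6/S5, S5/S4, S4/S3, S3/S2, S2/S1, S1/S0, S0/EXTRA.",
  "thresholds": [-16.0, -3.5, 0.0, 3.2, 6.4, 9.6, 12.8, 16.0],
  "capacity": {"S0": 2, "S1": 1, "S2": 1, "S3": 1, "S4": 1, "S5": 1, "S6": 1}
}
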