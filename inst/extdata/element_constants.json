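{
  "_comment": [
    "Synthetic default fundamental-parameter table for 17 keV excitation and a",
    "silicon drift detector. sigma_cm2_g is the K-fluorescence production",
    "cross-section (photoionization x fluorescence yield, cm^2/g), xi the",
    "detector efficiency at the Ka energy (dimensionless, includes window",
    "transmission), A_g_mol the atomic mass. f = sigma*xi/A is the total",
    "fundamental-parameter correction used by the areal-mass calibration.",
    "These are plausible order-of-magnitude defaults, NOT a certified",
    "instrument characterization: absolute areal masses computed with them",
    "are internally consistent but instrument-specific. Replace with your",
    "beamline's characterization for absolute work."
  ],
  "elements": [
    {"element": "Si", "sigma_cm2_g": 0.55, "xi": 0.25, "A_g_mol": 28.09},
    {"element": "P",  "sigma_cm2_g": 0.75, "xi": 0.35, "A_g_mol": 30.97},
    {"element": "S",  "sigma_cm2_g": 1.00, "xi": 0.45, "A_g_mol": 32.06},
    {"element": "Cl", "sigma_cm2_g": 1.30, "xi": 0.55, "A_g_mol": 35.45},
    {"element": "K",  "sigma_cm2_g": 2.20, "xi": 0.72, "A_g_mol": 39.10},
    {"element": "Ca", "sigma_cm2_g": 2.80, "xi": 0.80, "A_g_mol": 40.08},
    {"element": "Fe", "sigma_cm2_g": 7.60, "xi": 0.98, "A_g_mol": 55.85},
    {"element": "Zn", "sigma_cm2_g": 13.0, "xi": 0.97, "A_g_mol": 65.38}
  ]
}
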