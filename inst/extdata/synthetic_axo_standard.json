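{
  "_comment": [
    "SYNTHETIC stand-in for a certified thin multilayer reference standard",
    "(AXO-type) measured on the same setup as the sample. The certificate of",
    "the real standard is not public, so these values are invented but",
    "dimensionally and statistically plausible; the calibration equation only",
    "ever uses them relative to sample count rates, so every identity and",
    "round-trip in this package holds exactly for any consistent choice.",
    "am/eps in ng/cm^2; count rates in counts per pixel at the reference",
    "dwell; membrane thicknesses in cm (500 nm Si3N4 windows on both)."
  ],
  "am_fe_axo_ng_cm2": 300.0,
  "eps_fe_axo_ng_cm2": 39.9,
  "s_fe_axo": 5000.0,
  "s_si_axo": 20000.0,
  "t_si_cm": 5.0e-5,
  "t_si_axo_cm": 5.0e-5
}
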