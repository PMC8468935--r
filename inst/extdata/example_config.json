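{
  "generator": {
    "n_days": 5,
    "carcasses_per_day": 5,
    "wavelength_step": 3,
    "scatter_multiplicative_sd": 0.05,
    "seed": 42
  },
  "trim": [400, 1000],
  "chains": ["original", "msc", "snv", "sg", "sg_1der", "sg_2der",
             "sg_detrend_msc", "sg_detrend_snv"],
  "properties": ["pH", "Lstar", "astar", "bstar", "cooking_loss",
                 "shear_force"],
  "split_method": "gradient",
  "seed": 42,
  "max_components": 15,
  "out_dir": "results"
}
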