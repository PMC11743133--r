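{
  "version": "0.1.0",
  "model": {
    "a_B": 1.0,
    "Ea_B": 65000,
    "kappa_D": 5.0,
    "dH_m": 300000,
    "T_m": 315.0,
    "dCp": 0,
    "c": 0.1,
    "b": 0.75
  },
  "optimizer": {
    "M_bounds": [0.5, 30],
    "grid_n": 41,
    "refine": true,
    "reltol": 1e-08,
    "n_starts": 2,
    "seed": 1
  },
  "bootstrap": {
    "n_boot": 2000,
    "seed": 1
  },
  "simulate": {
    "seed": 1,
    "n_dishes_per_temp": 60,
    "n_controls_per_temp": 5
  }
}
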