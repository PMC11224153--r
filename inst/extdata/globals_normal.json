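{
  "globals": {
    "total_blood_volume": 5050,
    "hr0": 73.5,
    "p_intrathoracic": -3.5,
    "density_factor": 0.77
  },
  "reflex": {
    "set_point": 97.6,
    "sensor_tau": 3.3,
    "gains": {
      "hr": 0.05,
      "emax": 0.05,
      "r": 0.04,
      "vu": 0.03
    },
    "taus": {
      "hr": 2,
      "emax": 5,
      "r": 12,
      "vu": 12
    },
    "lo": {
      "hr": 0.4,
      "emax": 0.4,
      "r": 0.97,
      "vu": 0.72
    },
    "hi": {
      "hr": 2,
      "emax": 1.15,
      "r": 2.2,
      "vu": 1.4
    }
  },
  "lymph": {
    "from": ["leg_vein", "spl_vein", "ub_vein"],
    "to": ["svc", "svc", "svc"],
    "cond": [0.008, 0.008, 0.004]
  }
}
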