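{
  "WM": {
    "E_MPa": 0.0232,
    "rho_ton_per_mm3": 1.04e-09,
    "nu": 0.4999
  },
  "GM": {
    "E_MPa": 0.0232,
    "rho_ton_per_mm3": 1.04e-09,
    "nu": 0.4999
  },
  "CSF": {
    "E_MPa": 0.0232,
    "rho_ton_per_mm3": 1.04e-09,
    "nu": 0.4999
  },
  "HOMOG": {
    "E_MPa": 0.0232,
    "rho_ton_per_mm3": 1.04e-09,
    "nu": 0.4999
  }
}
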