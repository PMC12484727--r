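{
  "WM": {
    "E_MPa": 0.03103,
    "rho_ton_per_mm3": 1.05e-09,
    "nu": 0.45
  },
  "GM": {
    "E_MPa": 0.01537,
    "rho_ton_per_mm3": 1.05e-09,
    "nu": 0.45
  },
  "CSF": {
    "E_MPa": 0.299,
    "rho_ton_per_mm3": 1.05e-09,
    "nu": 0.45
  }
}
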