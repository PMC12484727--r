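{
  "WM": {
    "E_MPa": 0.001895,
    "rho_ton_per_mm3": 1.05e-09,
    "nu": 0.45
  },
  "GM": {
    "E_MPa": 0.001389,
    "rho_ton_per_mm3": 1.05e-09,
    "nu": 0.45
  },
  "CSF": {
    "E_MPa": 2.19,
    "rho_ton_per_mm3": 1e-09,
    "nu": 0.4999
  },
  "SKULL": {
    "E_MPa": 6000,
    "rho_ton_per_mm3": 3.5e-09,
    "nu": 0.22
  }
}
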