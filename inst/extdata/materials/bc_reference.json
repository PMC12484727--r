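{
  "WM": {
    "E_MPa": 0.497,
    "rho_ton_per_mm3": 1.14e-09,
    "nu": 0.48
  },
  "GM": {
    "E_MPa": 0.497,
    "rho_ton_per_mm3": 1.14e-09,
    "nu": 0.48
  },
  "CSF": {
    "E_MPa": 1.314,
    "rho_ton_per_mm3": 1.04e-09,
    "nu": 0.4999
  },
  "SKULL": {
    "E_MPa": 8000,
    "rho_ton_per_mm3": 4.79e-09,
    "nu": 0.22
  },
  "NECK": {
    "E_MPa": 8000,
    "rho_ton_per_mm3": 4.79e-09,
    "nu": 0.22
  },
  "SPINE": {
    "E_MPa": 8000,
    "rho_ton_per_mm3": 4.79e-09,
    "nu": 0.22
  }
}
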