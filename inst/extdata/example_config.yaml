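# Example msderep configuration.
# `adducts` extends the built-in adduct registry; `element_ranges`
# defines named range presets usable wherever ranges are accepted.
adducts:
  - name: "[M+2H]2+"
    charge: 2
    delta:
      H: 2
  - name: "[M+H-H2O]+"
    charge: 1
    delta:
      H: -1
      O: -1
element_ranges:
  broad_screen: "C0-100H0-200N0-20O0-20S0-10F0-3Cl0-3Br0-3B0-3"
  chno_only: "C0-50H0-100N0-10O0-10"
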