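# Scaled-down simulation configuration. Omitted fields fall back to the
# full-scale defaults (3.2 x 3.2 x 1.92 mm at 10 um, 0.96 mm agar, 1 ms
# sub-steps, Henry's-law oxygen, 2.5 g/L glucose).
lattice:
  dims: [64, 64, 48]
  agar_height: 1.6e-4
  dtau: 5.0e-3
run:
  hours: 12
  glucose_g_per_l: 2.5
  variant: regulated
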