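# Example model configuration: override any subset of the defaults.
pools:
  t1_water: 1.8        # s
  t2_water: 0.04       # s
  exchange_rate: 5500  # 1/s, glutamate amine
  solute_shift: 3.0    # ppm downfield of water
cest_saturation:
  b1_rms: 3.06         # uT
  duration: 0.8        # s
wassr_saturation:
  b1_rms: 0.29
  duration: 0.2
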