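# Cultivar coefficient registry for the alpha-acid accumulation model
#   alpha = (k2 + k3*w^2 - k1*w) / (10*x)   [% dry matter]
# x: effective temperature sum (degC.day, base 5) over F3..F9
# w: rainfall sum (mm) over F3..F9
# et0_threshold: mean July ET0 (mm/day) above which predictions are unreliable
Aurora:
  k1: 53.8
  k2: 453.0
  k3: 1.33
  et0_threshold: 4.5
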