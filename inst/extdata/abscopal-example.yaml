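# Example run configuration: fibrosarcoma-like primary treated with
# three 8 Gy fractions; the metastasis responds through the RT-triggered
# immune pulses (abscopal effect).
schema: gomptx/1
seed: 1
model: {a: 0.054, k: 0.0164, N0: 50, unit: mm^3}
grid: {from: 0, to: 40, by: 1}
therapy:
  rt:
    alpha: 0.3
    beta: 0.03
    fractions:
      - {day: 9, dose_Gy: 8}
      - {day: 10, dose_Gy: 8}
      - {day: 11, dose_Gy: 8}
  synergy: {delta: 1, tau: 5, lag: 3, Y0: 0.1, t_in: 9}
noise: {kind: multiplicative_lognormal, sd: 0}
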