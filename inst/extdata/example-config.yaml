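design:
  - "PT(1:1:1:1:1)"
  - "PT(1:1:1:1:k)"
n_drugs: 4
accrual_mean: [100, 200, 300, 400]
rp: [0.075, 0.10, 0.125, 0.15]
scenario: [2, 3, 4, 5]
n_reps: 1000
alpha: 0.05
seed: 20250217
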