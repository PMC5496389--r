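# Default cohort: three arms of 7 subjects each (the per-group N that
# completed imaging), Rician noise at SNR 20.
arms:
  "+HEM": 7
  "I-HEM": 7
  "I+HEM": 7
snr: 20
seed: 1
noise_model: rician
include_baseline: true
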