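# Infarct-only arm: 45 min occlusion with saline. Non-hemorrhagic infarct
# with notable edema, no MVO.
arm: "I-HEM"
noise:
  model: rician
  snr: 20
tissue:
  remote_t2: 38
  remote_t2star: 35
  edema_t2: 45.6      # ~20% over remote
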