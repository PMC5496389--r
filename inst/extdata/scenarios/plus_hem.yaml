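# Hemorrhage-only arm: intracoronary collagenase after a brief (8 min)
# occlusion. Hemorrhage and mild edema, no infarct, no MVO.
arm: "+HEM"
noise:
  model: rician
  snr: 20
tissue:
  remote_t2: 38
  remote_t2star: 35
  edema_t2: 45.2      # ~19% over remote
  edema_t2star: 25    # scattered iron across the injured territory
  hemorrhage_t2star: 12
  hemorrhage_t2: 25
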