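# Hemorrhagic infarct arm: 45 min occlusion with collagenase. Large infarct,
# considerable hemorrhage, MVO core.
arm: "I+HEM"
noise:
  model: rician
  snr: 20
mvo_fraction: 0.2
hemorrhage_fraction: 0.12   # longitudinal core, ~1.7 g at the default geometry
tissue:
  remote_t2: 38
  remote_t2star: 35
  edema_t2: 51.3      # ~35% over remote
  edema_t2star: 25    # scattered iron across the injured territory
  hemorrhage_t2star: 12
  hemorrhage_t2: 25
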