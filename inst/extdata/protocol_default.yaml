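# Stepwise vasoactive-infusion protocol: five infusion arms across three
# volume conditions; each arm ramps the drug through five dose steps of
# 10 min, with MAP and TOI sampled every 10 s (60 paired samples per step).
# Hypovolemia has no SNP arm (vasodilation during hypovolemia is lethal).
conditions:
  - baseline
  - hypovolemia
  - fluid_resuscitation
drugs_per_condition:
  baseline: [phenylephrine, SNP]
  hypovolemia: [phenylephrine]
  fluid_resuscitation: [phenylephrine, SNP]
dose_levels: [0, 0.5, 1, 2, 5]
step_duration: 600
sampling_interval: 10
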