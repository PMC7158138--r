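condition,drug,dose_ug_kg_min,map_mean,map_sd,toi_cerebral_mean,toi_cerebral_sd,toi_thoracic_mean,toi_thoracic_sd,toi_lumbar_mean,toi_lumbar_sd
baseline,phenylephrine,0,60,3,64.9,2.6,47.7,3.7,52.8,2.8
baseline,phenylephrine,0.5,64,3,64.5,2.9,47.6,3.8,53.3,2.7
baseline,phenylephrine,1,69,4,64.2,4.0,47.6,3.7,53.9,3.3
baseline,phenylephrine,2,80,7,63.4,4.3,48.4,3.8,54.6,3.9
baseline,phenylephrine,5,109,14,62.5,4.3,49.2,3.7,54.9,4.6
baseline,SNP,0,69,8,63.9,3.4,47.2,3.7,53.2,4.0
baseline,SNP,0.5,59,7,63.2,2.8,45.7,3.2,51.8,3.7
baseline,SNP,1,54,6,63.1,2.4,45.1,2.9,51.6,4.3
baseline,SNP,2,49,7,62.4,2.2,43.9,2.9,50.4,4.3
baseline,SNP,5,41,7,60.8,2.6,41.8,3.1,47.7,4.0
hypovolemia,phenylephrine,0,48,8,61.2,3.1,42.2,4.7,46.2,3.6
hypovolemia,phenylephrine,0.5,53,7,61.4,2.8,43.4,4.5,47.6,3.8
hypovolemia,phenylephrine,1,56,6,61.2,2.8,44.4,3.9,49.0,4.3
hypovolemia,phenylephrine,2,60,8,60.3,2.3,45.1,3.4,49.7,4.4
hypovolemia,phenylephrine,5,80,11,60.2,2.3,46.5,3.6,51.1,4.8
fluid_resuscitation,phenylephrine,0,60,7,61.0,3.5,45.7,4.2,50.1,4.3
fluid_resuscitation,phenylephrine,0.5,61,6,60.8,3.1,45.1,3.9,49.4,4.0
fluid_resuscitation,phenylephrine,1,64,8,60.6,2.9,45.1,3.5,49.4,3.8
fluid_resuscitation,phenylephrine,2,75,10,60.3,2.2,45.9,3.5,50.3,4.5
fluid_resuscitation,phenylephrine,5,102,21,59.4,2.0,46.2,3.8,50.7,5.1
fluid_resuscitation,SNP,0,56,7,60.2,3.0,43.9,2.9,48.1,4.0
fluid_resuscitation,SNP,0.5,48,5,59.0,2.4,41.9,2.7,46.0,3.9
fluid_resuscitation,SNP,1,44,5,58.8,3.2,41.6,2.5,45.7,4.8
fluid_resuscitation,SNP,2,39,5,57.5,2.6,40.4,2.7,44.2,4.6
fluid_resuscitation,SNP,5,34,3,54.7,3.0,38.4,2.6,41.1,3.2
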