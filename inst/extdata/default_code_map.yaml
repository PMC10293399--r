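ischemic_heart_disease:
- I20
- I21
- I22
- I23
- I24
- I25
peripheral_vascular_disease:
- I70
- I71
- I72
- I73
congestive_heart_failure:
- I50
- I11.0
- I13.0
- I13.2
copd:
- J40
- J41
- J42
- J43
- J44
hypertension:
- I10
- I11
- I12
- I13
- I15
diabetes_mellitus:
- E10
- E11
- E13
- E14
dementia:
- F00
- F01
- F02
- F03
- G30
stroke_hemiplegia:
- I60
- I61
- I62
- I63
- I64
- I69
- G81
chronic_renal_disease:
- N18
- N19
cancer:
- C0
- C1
- C2
- C3
- C4
- C5
- C6
- C7
- C8
- C9
parkinsons_disease:
- G20
- G21
- G22
arthritis:
- M05
- M06
- M15
- M16
- M17
- M18
- M19
reflux_peptic_ulcer:
- K21
- K25
- K26
- K27
- K28
chronic_liver_disease:
- K70
- K73
- K74
atrial_fibrillation:
- I48
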