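name,kind,pattern,pharmacologic
dual_energy_xray_absorptiometry,proc,CPT:77080,no
dual_energy_xray_absorptiometry,proc,CPT:77081,no
dual_energy_xray_absorptiometry,proc,CPT:77085,no
vertebral_fracture_assessment,proc,CPT:77086,no
quantitative_computed_tomography,proc,CPT:77078,no
other_bone_density_measurement,proc,CPT:76977,no
other_bone_density_measurement,proc,CPT:78350,no
other_bone_density_measurement,proc,CPT:77082,no
bone_turnover_markers,proc,CPT:82523,no
bone_turnover_markers,proc,CPT:83937,no
bisphosphonate,med,alendronate,yes
bisphosphonate,med,ibandronate,yes
bisphosphonate,med,risedronate,yes
bisphosphonate,med,zoledronic acid,yes
abaloparatide,med,abaloparatide,yes
denosumab,med,denosumab,yes
raloxifene,med,raloxifene,yes
bazedoxifene,med,bazedoxifene,yes
romosozumab,med,romosozumab,yes
teriparatide,med,teriparatide,yes
calcitonin,med,calcitonin,yes
osteoporosis_diagnosis,dx,ICD10:M80,no
osteoporosis_diagnosis,dx,ICD10:M81,no
osteoporosis_diagnosis,dx,ICD9:733.0,no
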