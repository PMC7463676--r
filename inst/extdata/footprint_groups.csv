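variable,group
glucose_0,milieu
glucose_30,milieu
glucose_120,milieu
insulin_0,milieu
insulin_30,milieu
insulin_120,milieu
cpeptide_0,milieu
cpeptide_30,milieu
cpeptide_120,milieu
ffa_0,milieu
ffa_30,milieu
ffa_120,milieu
auc_glucose,milieu
auc_insulin,milieu
auc_cpeptide,milieu
auc_ffa,milieu
hba1c,milieu
age,milieu
bmi,milieu
waist,milieu
tg,milieu
hdl,milieu
homa_b,mechanisms
homa_ir,mechanisms
ratio_cpep_glu_030,mechanisms
ratio_ins_glu_030,mechanisms
igi,mechanisms
delta_cpep_glu_030,mechanisms
di,mechanisms
matsuda,mechanisms
liver_ir,mechanisms
hepatic_ir,mechanisms
adipo_ir,mechanisms
isi_ffa,mechanisms
ic_fast,mechanisms
ic_delta_030,mechanisms
ic_120,mechanisms
nafld_fls,pathology
fli,pathology
egfr,pathology
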