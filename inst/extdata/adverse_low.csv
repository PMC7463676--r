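variable
matsuda
isi_ffa
di
egfr
ic_fast
ic_120
homa_b
igi
delta_cpep_glu_030
ratio_cpep_glu_030
ratio_ins_glu_030
hdl
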