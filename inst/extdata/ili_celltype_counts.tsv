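cell_type	count
CD4_Naive_T	5821
CD4_Effector_T	360
CD4_Effector_Memory_T	716
CD8_Naive_T	760
CD8_Effector_T	5022
CD8_Effector_Memory_T	3036
NKT	1382
NK	6378
B	6231
CD14_Mono	14377
CD16_Mono	1652
cDC	272
Proliferating	771
PLT	3636
RBC	829
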