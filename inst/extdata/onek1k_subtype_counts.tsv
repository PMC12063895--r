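source	count	target
CD4 Naive	255130	CD4_Naive_T
CD4 CTL	17849	CD4_Effector_T
CD4 TEM	30879	CD4_Effector_Memory_T
CD8 Naive	51487	CD8_Naive_T
CD8 TCM	16175	CD8_Effector_T
CD8 TEM	159634	CD8_Effector_Memory_T
NK	160465	NKT
NK_CD56bright	6922	NK
B naive	64321	B_memory
B intermediate	29466	B_memory
B memory	29474	B_memory
CD14 Mono	35560	CD14_Monocyte
CD16 Mono	15502	CD16_Monocyte
cDC1	114	cDC
cDC2	4401	cDC
CD4 Proliferating	762	Proliferating
CD8 Proliferating	304	Proliferating
NK Proliferating	1704	Proliferating
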