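phylum	total	saliva	tongue	n_sig
Firmicutes	6305	2223	4082	91
Bacteroidota	1846	975	871	13
Actinobacteriota	1820	858	962	19
Proteobacteria	1287	507	780	16
Fusobacteriota	975	416	559	10
Others	3289	1378	1911	56
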