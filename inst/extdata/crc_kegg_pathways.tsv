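pathway_id	description	p_adj
hsa04657	IL-17 signaling pathway	9.27e-06
hsa04668	TNF signaling pathway	3.79e-04
hsa04620	Toll-like receptor signaling pathway	4.21e-03
hsa04913	Ovarian steroidogenesis	7.08e-03
hsa04064	NF-kappa B signaling pathway	4.53e-02
hsa01523	Antifolate resistance	4.67e-02
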