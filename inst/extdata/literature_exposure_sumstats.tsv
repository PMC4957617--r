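snp	effect_allele	other_allele	trait	beta	se	n
rs11977526	A	G	IGF2	94.78	14.4413265306122	718
rs11977526	A	G	IGFBP3	83.98	58.7551020408163	712
rs11977526	A	G	IGF1	3.07	2.97959183673469	727
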