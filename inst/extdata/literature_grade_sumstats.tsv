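snp	effect_allele	other_allele	outcome	beta	se	n
rs11977526	A	G	grade	0.048790164169432	0.0243138213786543	18342
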