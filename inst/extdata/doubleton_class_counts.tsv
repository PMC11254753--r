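class	D	hom_obs	N
missense	1580917	5857	821979
synonymous	679335	2490	821979
plof	129405	406	821979
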