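exposure	mediator	outcome	or_xy	ci_low_xy	ci_high_xy	or_xm	ci_low_xm	ci_high_xm	or_my	ci_low_my	ci_high_my	type	effect_rate
UC	MO superior fronto-occipital fasciculus R	pain	1.019	1.008	1.030	1.142	1.035	1.260	1.062	1.025	1.101	PM	42.43
UC	T1 FAST ROIs R parahippocampal gyrus posterior	pain	1.019	1.008	1.030	1.037	1.009	1.065	1.066	1.053	1.079	PM	12.33
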