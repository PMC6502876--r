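pair	group	coverage
1055f-1392r	EUB	0.445
1055f-1392r	AOB	0.829
1055f-1392r	AnAOB	0.830
1055f-1392r	Nitrobacter	0.857
1055f-1392r	Nitrospira	0.716
338f-518r	EUB	0.700
338f-518r	AOB	0.410
338f-518r	AnAOB	0
338f-518r	Nitrobacter	0.360
338f-518r	Nitrospira	0.370
341f-543r	EUB	0.512
341f-543r	AOB	0.940
341f-543r	AnAOB	0
341f-543r	Nitrobacter	0.860
341f-543r	Nitrospira	0.007
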