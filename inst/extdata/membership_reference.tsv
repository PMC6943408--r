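species	MP	Pro	MDA	SOD	POD
Hypnum leptothallum	0.8346	1.0000	1.0000	0.9618	0.3549
Racopilum cuspidigerum	0.5984	0.4690	0.9877	1.0000	0.5374
Hyophila involuta	0.3226	0.0201	0.5825	0.8835	1.0000
Anomodon viticulosus	0.8035	0.2791	0.9767	0.0000	0.3351
Plagiomnium cuspidatum	1.0000	0.2464	0.3315	0.2927	0.1929
Thuidium kanedae	0.5258	0.8827	0.0000	0.3726	0.0109
Meteorium polytrichum	0.0000	0.0000	0.2864	0.6273	0.0000
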