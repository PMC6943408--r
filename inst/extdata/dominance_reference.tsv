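species	species_frequency	sn_s	sn_na	na_ta
Hypnum leptothallum	39.5	0.118	6.636	0.786
Didymodon fallax	21.6	0.059	3.333	0.857
Bryum recurvulum	14.6	0.040	3.222	0.357
Hyophila involuta	13.5	0.037	5.400	0.857
Thuidium kanedae	13.5	0.037	3.571	0.500
Hyophila javanica	12.4	0.034	2.000	0.643
Bryum argenteum	11.9	0.033	2.556	0.714
Trichostomum crispulum	10.8	0.030	2.200	0.643
Palamocladium euchloron	10.8	0.030	2.500	0.571
Didymodon constrictus var. constrictus	9.7	0.027	2.143	0.643
Barbula unguiculata	8.1	0.022	1.875	0.500
Anomodon viticulosus	8.1	0.022	5.000	0.214
Ptychomitrium gardneri	8.1	0.022	1.875	0.571
Meteorium polytrichum	8.1	0.022	1.857	0.571
Plagiomnium cuspidatum	6.5	0.018	3.000	0.286
Bryum funkii	5.9	0.016	1.833	0.429
Weissia breviseta	5.4	0.015	1.667	0.429
Racopilum cuspidigerum	5.4	0.015	2.500	0.286
Bryum algovicum	4.3	0.012	1.333	0.429
Eurhynchium eustegium	4.3	0.012	2.000	0.286
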