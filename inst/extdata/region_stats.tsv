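sample_id	total_positions	exon	exon_percent	intron	intron_percent	intergenic	intergenic_percent	spliced	spliced_percent
SC1	120604217	92309005	76.54	860430	0.71	4794472	3.98	22640310	18.77
SC2	120489277	84173841	69.86	1248829	1.04	5752705	4.77	29313902	24.33
SC3	115039494	83651248	72.72	1110422	0.97	7031767	6.11	23246057	20.21
ST1	191954792	131590789	68.55	1479338	0.77	21420452	11.16	37464213	19.52
ST2	121649971	84829641	69.73	1075848	0.88	11366864	9.34	24377618	20.04
ST3	112121097	76909155	68.59	1401805	1.25	9872787	8.81	23937350	21.35
TC1	124254032	84405467	67.93	1029079	0.83	14506377	11.67	24313109	19.57
TC2	110100967	85954481	78.07	510469	0.46	4602925	4.18	19033092	17.29
TC3	105698981	73161750	69.22	1069136	1.01	6573728	6.22	24894367	23.55
TT1	113772045	76581286	67.31	1747207	1.54	6621542	5.82	28822010	25.33
TT2	147430188	100277333	68.02	1518413	1.03	15045184	10.2	30589258	20.75
TT3	110358555	75782160	68.67	1472869	1.33	6061655	5.49	27041871	24.5
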