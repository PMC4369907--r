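sample_id	n_transcripts	average_size	n50	known_count	known_percent	known_genes	novel_count	novel_percent	novel_genes
SC1	35975	1469.6	1831	33235	92.38	21914	2740	7.62	2194
SC2	39333	1507.2	1899	36022	91.58	23528	3311	8.42	2663
SC3	38489	1508.6	1886	35178	91.40	22720	3311	8.60	2641
ST1	40989	1394.4	1802	37256	90.89	23998	3733	9.11	2987
ST2	40125	1544.6	1926	36540	91.07	23780	3585	8.93	2837
ST3	40972	1584.6	1983	37026	90.37	23759	3946	9.63	3191
TC1	38268	1526.1	1902	35268	92.16	23205	3000	7.84	2398
TC2	35272	1264.2	1547	32639	92.54	22862	2633	7.46	2179
TC3	38507	1528.8	1903	35518	92.24	23539	2989	7.76	2397
TT1	42377	1590.2	2007	38090	89.88	24419	4287	10.12	3458
TT2	40585	1399.2	1823	36939	91.02	23603	3646	8.98	2896
TT3	41515	1557.1	1969	37273	89.78	24214	4242	10.22	3443
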