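sample_id	raw_reads	hq_reads	hq_percent	mapped_reads	mapped_percent
SC1	110445132	102110944	92.45	81760543	80.07
SC2	118361874	109714376	92.69	87250440	79.53
SC3	108124090	99783462	92.29	79232619	79.4
ST1	122256502	114109402	93.34	88945294	77.95
ST2	109367326	102743400	93.94	80030194	77.89
ST3	106564594	99517680	93.39	77090356	77.46
TC1	108790978	102039304	93.79	79933511	78.34
TC2	105514112	99385790	94.19	80911686	81.41
TC3	102595286	96561142	94.12	76501404	79.23
TT1	117028020	108822936	92.99	84948725	78.06
TT2	117708038	109660302	93.16	85938332	78.37
TT3	114845464	106774882	92.97	83835866	78.52
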