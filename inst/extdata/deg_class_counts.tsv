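set	class	count
deg_hs	up	3226
deg_hs	down	2158
deg_ht	up	2755
deg_ht	down	2772
deg_overlap	up_both	843
deg_overlap	down_both	769
deg_overlap	upT_downS	16
deg_overlap	downT_upS	33
htrt	up_both	19
htrt	down_both	4
htrt	upT_downS	4
htrt	downT_upS	8
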