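peak_index	name	mz	rt_s	estimated_ppb	nominal_ppb
1	heroin	370.1643	685.3724	507.4039	500
2	morphine	286.1431	146.2696	499.5544	500
3	cocaine	304.1538	701.1360	501.2351	500
4	thebaine	312.1588	678.8176	450.4228	500
5	delta9-THC	315.2302	1513.3190	467.1095	500
6	amphetamine	136.0804	419.1944	773.8217	500
7	MA	150.1021	496.8365	595.2049	500
8	MDMA	194.1173	538.9991	520.7164	500
9	MDA	180.0866	505.6407	492.0814	500
10	ketamine	238.0988	599.9313	547.7417	500
11	FM2	314.0930	1044.2740	512.0763	500
12	nimetazepam	296.1024	1040.5220	537.2955	500
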