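peak_index	name	estimated_mz	formula	hmdb_id
1	heroin	370.1642	C21H23NO5	NA
2	morphine	286.1430	C17H19NO3	HMDB0014440
3	cocaine	304.1538	C17H21NO4	HMDB0015043
4	thebaine	312.1586	C19H21NO3	HMDB0029378
5	delta9-THC	315.2318	C21H30O2	HMDB0014613
6	amphetamine	136.1118	C9H13N	HMDB0014328
7	MA	150.1273	C10H15N	HMDB0015517
8	MDMA	194.1172	C11H15NO2	HMDB0254382
9	MDA	180.1017	C10H13NO2	HMDB0041931
10	ketamine	238.0992	C13H16ClNO	HMDB0015352
11	FM2	314.0930	C16H12FN3O3	HMDB0015510
12	nimetazepam	296.1025	C16H13N3O3	NA
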