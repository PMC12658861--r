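db_name	db_id	xref_id	name	formula	monoisotopic_mass
HMDB	HMDB0014440	C01516	morphine	C17H19NO3	NA
HMDB	HMDB0015043	C01416	cocaine	C17H21NO4	NA
HMDB	HMDB0029378	C06173	thebaine	C19H21NO3	NA
HMDB	HMDB0014613	C06972	delta9-tetrahydrocannabinol	C21H30O2	NA
HMDB	HMDB0014328	C07514	amphetamine	C9H13N	NA
HMDB	HMDB0015517	C07164	methamphetamine	C10H15N	NA
HMDB	HMDB0254382	C07577	MDMA	C11H15NO2	NA
HMDB	HMDB0041931	C07576	MDA	C10H13NO2	NA
HMDB	HMDB0015352	C07525	ketamine	C13H16ClNO	NA
HMDB	HMDB0015510	C07826	flunitrazepam	C16H12FN3O3	NA
MassBank	MB-SYN-000001	NA	heroin	C21H23NO5	NA
MassBank	MB-SYN-000002	NA	nimetazepam	C16H13N3O3	NA
HMDB	HMDB0000122	C00031	D-glucose	C6H12O6	NA
HMDB	HMDB0000161	C00041	L-alanine	C3H7NO2	NA
HMDB	HMDB0000517	C00062	L-arginine	C6H14N4O2	NA
HMDB	HMDB0000687	C00123	L-leucine	C6H13NO2	NA
HMDB	HMDB0000158	C00082	L-tyrosine	C9H11NO3	NA
HMDB	HMDB0000289	C00086	urea	CH4N2O	NA
HMDB	HMDB0000562	C00791	creatinine	C4H7N3O	NA
HMDB	HMDB0000064	C00300	creatine	C4H9N3O2	NA
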