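pathway_id	pathway_name	type	a	b	sign	relation	category
demo01	sugar interconversion	node	G0001	gene		 	metabolism
demo01	sugar interconversion	node	G0002	gene		 	metabolism
demo01	sugar interconversion	node	C0001	compound		 	metabolism
demo01	sugar interconversion	node	C0002	compound		 	metabolism
demo01	sugar interconversion	edge	G0001	C0001	activation	ECrel	metabolism
demo01	sugar interconversion	edge	C0001	C0002	1	compound	metabolism
demo01	sugar interconversion	edge	G0002	C0002	inhibition	ECrel	metabolism
demo02	signalling cascade	node	G0003	gene		 	signalling
demo02	signalling cascade	node	G0004	gene		 	signalling
demo02	signalling cascade	node	G0005	gene		 	signalling
demo02	signalling cascade	edge	G0003	G0004	activation	PPrel	signalling
demo02	signalling cascade	edge	G0004	G0005	-1	PPrel	signalling
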