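medium	element	mass_fraction
bone	H	3.50
bone	C	16.00
bone	N	4.20
bone	O	44.50
bone	Na	0.30
bone	Mg	0.20
bone	P	9.50
bone	S	0.30
bone	Ca	21.50
bone_marrow	H	10.50
bone_marrow	C	41.40
bone_marrow	N	3.40
bone_marrow	O	43.90
bone_marrow	Na	0.10
bone_marrow	Mg	0.20
bone_marrow	P	0.20
bone_marrow	S	0.20
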