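radical	site	isotope	Axx	Axy	Axz	Ayy	Ayz	Azz	frame	provenance
FAD	H3	1H	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	H6	1H	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	H7alpha1	1H	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	H7alpha2	1H	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	H7alpha3	1H	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	H8alpha1	1H	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	H8alpha2	1H	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	H8alpha3	1H	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	H9	1H	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	H1prime1	1H	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	H1prime2	1H	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	N1	14N	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	N3	14N	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	N5	14N	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	N10	14N	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	C2	13C	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	C4	13C	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	C4a	13C	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	C5a	13C	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	C6	13C	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	C7	13C	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	C8	13C	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	C9	13C	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	C9a	13C	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	C10a	13C	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	C7alpha	13C	0	0	0	0	0	0	flavin	synthetic-placeholder
FAD	C8alpha	13C	0	0	0	0	0	0	flavin	synthetic-placeholder
Trp	N1	14N	0	0	0	0	0	0	flavin	synthetic-placeholder
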