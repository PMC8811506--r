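gene_symbol	role	family	present_xtr	present_L	present_S	identity_pct	dnds_L	dnds_S	category_embryonic	category_tissue	notes
cxcl2	ligand	CXC	1	1	1	80	0.43	0.42	inc:DE	NCDE	Maternal S dominant expression
cxcl8a.1	ligand	CXC	1	1	1	87	0.18	0.29	inc:NA	inc:HC	Embryonic L dominant expression
cxcl8a.2	ligand	CXC	1	1	1	89	0.95	0.44	n/a	inc:HC	
cxcl8b.1	ligand	CXC	1	1	1	68	0.49	2.13	inc:NA	NCDE	Maternal L dominant expression
cxcl8b.2	ligand	CXC	1	1	0	NA	NA	NA	NA	NA	L singleton
cxcl9	ligand	CXC	1	0	1	NA	NA	NA	NA	NA	S singleton
cxcl10	ligand	CXC	1	1	1	92	0.16	0.51	n/a	HCDE	
cxcl11	ligand	CXC	1	1	1	78	0.37	0.65	n/a	inc	
cxcl12	ligand	CXC	1	1	1	93	0.1	0.41	inc:DE	NCDE	Embryonic L dominant expression
cxcl13a	ligand	CXC	1	1	1	86	0.22	0.69	n/a	HCSE	Maternal cxcl13a.L expression
cxcl13b	ligand	CXC	1	1	0	NA	NA	NA	NA	NA	L singleton
cxcl14	ligand	CXC	1	1	0	NA	NA	NA	NA	NA	Embryonic expression (L singleton)
cxcl16	ligand	CXC	1	1	1	63	0.81	0.61	n/a	inc:HC	Unidentified in teleosts
cxcl18	ligand	CXC	1	1	1	72	0.96	1.88	n/a	inc:SE	Unidentified in mammals
ccl5	ligand	CC	1	1	1	89	0.58	0.6	n/a	HCDE	Unidentified in teleosts
ccl19	ligand	CC	1	1	1	84	0.6	0.37	n/a	HCDE	
ccl20a	ligand	CC	1	1	1	72	0.25	0.39	n/a	HCSE	
ccl20b	ligand	CC	1	1	1	83	0.41	0.24	n/a	HCDE	
ccl20c	ligand	CC	1	0	0	NA	NA	NA	NA	NA	No syntenic ortholog in X. laevis
ccl21	ligand	CC	1	1	1	60	0.68	1.04	n/a	HCSE	Unidentified in teleosts
ccl25	ligand	CC	1	1	0	NA	NA	NA	NA	NA	Embryonic expression (L singleton)
ccl27	ligand	CC	0	1	0	NA	NA	NA	NA	NA	Unidentified in X. tropicalis (N deletion)
ccl28	ligand	CC	1	1	0	NA	NA	NA	NA	NA	Unidentified in teleosts; L singleton
ccl34a	ligand	CC	1	1	1	80	0.2	0.42	n/a	inc:HC	Unidentified in mammals
ccl34b	ligand	CC	1	1	1	NA	0.5	0.38	n/a	NA	Unidentified in mammals; newly identified, no tissue expression data
ccl42a	ligand	CC	1	1	1	73	0.49	0.59	n/a	HCSE	Unidentified in teleosts
ccl42b	ligand	CC	1	1	1	73	0.05	0.56	n/a	inc:NA	Unidentified in teleosts
ccl42c	ligand	CC	1	1	1	45	0.24	0.57	n/a	HCDE	Embryonic L dominant expression; unidentified in teleosts
ccl42d	ligand	CC	1	1	0	NA	NA	NA	NA	NA	Unidentified in teleosts; L singleton
xcl1	ligand	XC	1	1	1	75	1.96	0.4	n/a	HCDE	Unidentified in teleosts
xcl2	ligand	XC	1	1	1	72	1	0.94	n/a	inc:NA	Unidentified in teleosts
cxcr1	receptor	CXC	1	1	1	93	0.16	0.11	NCSE	HCDE	Embryonic S dominant expression
cxcr3	receptor	CXC	1	1	1	81	0.74	0.57	n/a	HCDE	
cxcr3l	receptor	CXC	1	1	1	89	0.22	0.39	n/a	inc:HC	Unidentified in mammals
cxcr4	receptor	CXC	1	1	1	97	0.02	0.06	HCSE	HCDE	Embryonic even expression
cxcr5	receptor	CXC	1	1	1	79	0.43	0.36	n/a	HCSE	
cxcr6	receptor	CXC	1	1	0	NA	NA	NA	NA	NA	L singleton
ackr3	receptor	CXC	1	1	1	97	0.07	0.06	HCDE	HCDE	Also known as cxcr7; embryonic L dominant expression
ackr4	receptor	CC	1	1	0	NA	NA	NA	NA	NA	Also known as ccrl1; L singleton
ccr2	receptor	CC	1	1	1	80	0.55	0.73	n/a	inc:NA	Maternal ccr2.L expression; unidentified in teleosts
ccr6	receptor	CC	1	1	0	NA	NA	NA	NA	NA	L singleton
ccr7	receptor	CC	1	1	1	87	0.34	0.3	n/a	HCSE	
ccr8	receptor	CC	1	1	0	NA	NA	NA	NA	NA	Maternal expression (L singleton); unidentified in teleosts
ccr9	receptor	CC	1	1	0	NA	NA	NA	NA	NA	L singleton
ccr10	receptor	CC	1	1	0	NA	NA	NA	NA	NA	L singleton
xcr1	receptor	XC	1	1	0	NA	NA	NA	NA	NA	L singleton
xcr2	receptor	XC	1	1	1	86	0.56	0.17	n/a	NA	
xcr3	receptor	XC	1	1	0	NA	NA	NA	NA	NA	L singleton
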