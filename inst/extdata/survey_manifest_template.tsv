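# Survey manifest TEMPLATE. Chain identifiers and author-numbered domain
# boundaries MUST be curated from each deposited entry (SEQRES / author
# annotations) before running the survey on real structures; the pipeline
# raises a hard error if a declared chain is absent. One example per MHC
# class is spelled out below with the conventional chain layout; every
# other entry needs the CURATE fields replaced.
entry_id	complex_index	chain_id	molecule	domain_name	start	end	species
2IAM	1	A	MHCII-a	a1	1	84	human
2IAM	1	A	MHCII-a	a2	85	182	human
2IAM	1	B	MHCII-b	b1	1	95	human
2IAM	1	B	MHCII-b	b2	96	190	human
2IAM	1	C	peptide	peptide	1	15	human
2IAM	1	D	TCRa	Va	1	107	human
2IAM	1	D	TCRa	Ca	117	202	human
2IAM	1	E	TCRb	Vb	1	113	human
2IAM	1	E	TCRb	Cb	118	245	human
1BD2	1	A	MHCI-heavy	a1	1	90	human
1BD2	1	A	MHCI-heavy	a2	91	182	human
1BD2	1	A	MHCI-heavy	a3	183	276	human
1BD2	1	B	b2m	b2m	1	99	human
1BD2	1	C	peptide	peptide	1	9	human
1BD2	1	D	TCRa	Va	1	107	human
1BD2	1	D	TCRa	Ca	117	202	human
1BD2	1	E	TCRb	Vb	1	113	human
1BD2	1	E	TCRb	Cb	118	245	human
1FYT	1	CURATE	TCRa	Ca	117	202	human
1J8H	1	CURATE	TCRa	Ca	117	202	human
1MI5	1	CURATE	TCRa	Ca	117	202	human
1OGA	1	CURATE	TCRa	Ca	117	202	human
1QSE	1	CURATE	TCRa	Ca	117	202	human
1ZGL	1	CURATE	TCRa	Ca	117	202	human
2AK4	1	CURATE	TCRa	Ca	117	202	human
2CKB	1	CURATE	TCRa	Ca	118	208	mouse
2PYF	1	CURATE	TCRa	Ca	117	202	human
2WBJ	1	CURATE	TCRa	Ca	117	202	human
3C5Z	1	CURATE	TCRa	Ca	118	208	mouse
3C6O	1	CURATE	TCRa	Ca	118	208	mouse
3FFC	1	CURATE	TCRa	Ca	117	202	human
3HG1	1	CURATE	TCRa	Ca	117	202	human
3MBE	1	CURATE	TCRa	Ca	118	208	mouse
3PL6	1	CURATE	TCRa	Ca	117	202	human
3RDT	1	CURATE	TCRa	Ca	118	208	mouse
3RGV	1	CURATE	TCRa	Ca	118	208	mouse
3SJV	1	CURATE	TCRa	Ca	117	202	human
3TOE	1	CURATE	TCRa	Ca	117	202	human
1NFD	1	CURATE	TCRa	Ca	118	208	mouse
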