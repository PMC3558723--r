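entry_id	mhc_class	species	n_complexes_reported	reported_contact
1BD2	I	human	1	Ca contacts TCR Vb
1FYT	II	human	1	Ca contacts MHCII b2
1J8H	II	human	1	Ca contacts MHCII b2
1MI5	I	human	1	Ca contacts TCR Vb
1OGA	I	human	1	Ca contacts TCR Vb
1QSE	I	human	1	Ca contacts MHCI b1
1ZGL	II	human	4	Two Ca contact TCR Vb, the other MHCII b2
2AK4	I	human	4	Two Ca contact MHCI a3/b2, the other a3
2CKB	I	mouse	1	Ca contacts the elbow of TCR Vb-Cb
2IAM	II	human	1	Ca contacts MHCII b2
2PYF	I	human	1	Ca contacts TCR Ca and Cb
2WBJ	II	human	2	One Ca contacts MHCII a2, the other has no contact
3C5Z	II	mouse	2	One Ca contacts TCR Vb, the other Cb
3C6O	II	mouse	2	One Ca contacts MHC a2, and the other Vb-Cb
3FFC	I	human	1	Ca forms dimer. FG loop and G strand are involved
3HG1	I	human	1	Ca barely contacts Vb
3MBE	II	mouse	1	Ca forms dimer. F and G strands are involved
3PL6	II	human	1	Ca contacts MHCII b2
3RDT	II	mouse	1	Ca contacts MHCII a2
3RGV	I	mouse	1	Ca contacts MHCI peptide-binding domains
3SJV	I	human	4	All Ca contact the MHCI peptide-binding domain
3TOE	II	human	1	Ca contacts CD4 only (TCR/pMHC/CD4 ternary complex)
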