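species	element	start	end
mouse	A	1	13
mouse	AB	14	21
mouse	B	22	28
mouse	BC	29	32
mouse	C	33	38
mouse	CD	39	44
mouse	D	45	50
mouse	DE	51	55
mouse	E	56	62
mouse	EF	63	72
mouse	F	73	79
mouse	FG	80	86
mouse	G	87	91
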