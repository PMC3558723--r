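species	element	start	end
human	A	1	13
human	AB	14	21
human	B	22	28
human	BC	29	32
human	C	33	38
human	CD	39	44
human	D	45	50
human	DE	51	55
human	E	56	62
human	EF	63	72
human	F	73	81
human	FG	82	88
human	G	89	95
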