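fixture	chain	resno	dssp
dimer	A	6	 
dimer	A	7	H
dimer	A	8	H
dimer	A	9	H
dimer	A	10	H
dimer	A	11	H
dimer	A	12	H
dimer	A	13	H
dimer	A	14	H
dimer	A	15	H
dimer	A	16	H
dimer	A	17	H
dimer	A	18	H
dimer	A	19	H
dimer	A	20	H
dimer	A	21	H
dimer	A	22	H
dimer	A	23	H
dimer	A	24	H
dimer	A	25	H
dimer	A	26	H
dimer	A	27	H
dimer	A	28	H
dimer	A	29	H
dimer	A	30	H
dimer	A	31	H
dimer	A	32	H
dimer	A	33	H
dimer	A	34	H
dimer	A	35	H
dimer	A	36	H
dimer	A	37	H
dimer	A	38	H
dimer	A	39	H
dimer	A	40	H
dimer	A	41	H
dimer	A	42	 
dimer	B	6	 
dimer	B	7	H
dimer	B	8	H
dimer	B	9	H
dimer	B	10	H
dimer	B	11	H
dimer	B	12	H
dimer	B	13	H
dimer	B	14	H
dimer	B	15	H
dimer	B	16	H
dimer	B	17	H
dimer	B	18	H
dimer	B	19	H
dimer	B	20	H
dimer	B	21	H
dimer	B	22	H
dimer	B	23	H
dimer	B	24	H
dimer	B	25	H
dimer	B	26	H
dimer	B	27	H
dimer	B	28	H
dimer	B	29	H
dimer	B	30	H
dimer	B	31	H
dimer	B	32	H
dimer	B	33	H
dimer	B	34	H
dimer	B	35	H
dimer	B	36	H
dimer	B	37	H
dimer	B	38	H
dimer	B	39	H
dimer	B	40	H
dimer	B	41	H
dimer	B	42	 
unfold	A	6	 
unfold	A	7	H
unfold	A	8	H
unfold	A	9	H
unfold	A	10	H
unfold	A	11	H
unfold	A	12	H
unfold	A	13	H
unfold	A	14	H
unfold	A	15	H
unfold	A	16	H
unfold	A	17	H
unfold	A	18	H
unfold	A	19	S
unfold	A	20	 
unfold	A	21	 
unfold	A	22	 
unfold	A	23	 
unfold	A	24	 
unfold	A	25	 
unfold	A	26	 
unfold	A	27	 
unfold	A	28	 
unfold	A	29	 
unfold	A	30	 
unfold	A	31	 
unfold	A	32	 
unfold	A	33	 
unfold	A	34	 
unfold	A	35	 
unfold	A	36	 
unfold	A	37	 
unfold	A	38	 
unfold	A	39	 
unfold	A	40	 
unfold	A	41	 
unfold	A	42	 
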