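name	complex	min_start	min_end	max_start	max_end
delA1	cxA	4000001	12000000	3500001	12800000
delA2	cxA	5500001	9000000	5000001	9600000
delA3	cxA	6200001	7400000	6000001	7800000
delB1	cxB	22000001	34000000	21200001	34900000
delB2	cxB	24500001	30000000	24000001	30700000
delB3	cxB	26000001	27500000	25600001	28100000
delC1	cxC	44000001	54000000	43200001	54800000
delC2	cxC	46500001	50500000	46000001	51200000
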