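chain_id	region	start	end
H	FW1	1	25
H	CDR1	26	33
H	FW2	34	50
H	CDR2	51	58
H	FW3	59	96
H	CDR3	97	108
H	FW4	109	120
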