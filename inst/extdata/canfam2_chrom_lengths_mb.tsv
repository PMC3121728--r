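chrom	length_mb
CFA1	125
CFA2	88
CFA3	95
CFA4	91
CFA5	92
CFA6	80
CFA7	83
CFA8	77
CFA9	64
CFA10	72
CFA11	77
CFA12	76
CFA13	66
CFA14	64
CFA15	67
CFA16	60
CFA17	67
CFA18	56
CFA19	55
CFA20	61
CFA21	54
CFA22	64
CFA23	55
CFA24	51
CFA25	54
CFA26	42
CFA27	49
CFA28	44
CFA29	44
CFA30	43
CFA31	42
CFA32	41
CFA33	34
CFA34	47
CFA35	29
CFA36	33
CFA37	33
CFA38	26
CFAX	127
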