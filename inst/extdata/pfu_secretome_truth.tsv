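id	sp_class	cleavage_after
PF1109	SPASE_I	24
PF1209	SPASE_I	24
PF1399	SPASE_I	25
PF0477	SPASE_I	26
PF1935	SPASE_I	26
PF0190	SPASE_I	28
PF1505	SPASE_I	24
PF1938	LIPOPROTEIN	22
PF1408	LIPOPROTEIN	22
PF0119	LIPOPROTEIN	20
PF1774	LIPOPROTEIN	18
PF1695	LIPOPROTEIN	21
PF0337	CLASS_III	4
PF0287	CLASS_III	5
PF1304	CLASS_III	4
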