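sample	group	n_ecc	mean_length	min_length	max_length	n_with_gene	n_with_trna	pct_with_cds_printed
CC2R	HR	4812	7058	31	28980	1031	53	21.43
CC2S	HS	4233	6994	60	25087	1010	77	23.86
CC5R	HR	5288	6946	51	29081	1145	74	21.65
CC5S	HS	4332	7002	54	28260	958	45	22.11
Peldon	HR	4443	6868	36	26368	962	59	21.65
Lola91	HR	5426	6918	49	27814	1153	70	21.25
Roth	HS	5663	7040	51	27090	1291	70	22.8
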