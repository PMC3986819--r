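gene	class	state	cds_len	tx_len	ptc_codon	fs_pos	n_cod
a001	autosome	autosome	474	1452	NA	NA	158.000000
a002	autosome	autosome	693	1348	NA	NA	231.000000
a003	autosome	autosome	888	1353	NA	NA	296.000000
g001	neo	normal	714	906	NA	NA	238.000000
g002	neo	normal	453	1095	NA	67	151.000000
g003	neo	normal	450	621	NA	NA	150.000000
g004	neo	normal	621	1244	NA	NA	207.000000
g005	neo	normal	897	1378	NA	603	299.000000
g006	neo	normal	450	704	NA	NA	150.000000
g007	neo	normal	450	854	NA	NA	150.000000
g008	neo	neoY_silenced	450	887	NA	NA	150.000000
g009	neo	normal	450	847	NA	NA	150.000000
g010	neo	normal	789	1372	NA	NA	263.000000
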