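gene	ptc_codon	fs_pos	fs_type	fs_len
g002	NA	67	del	4
g005	NA	603	del	1
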