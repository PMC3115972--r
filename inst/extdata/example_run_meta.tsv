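key	value
tiled_target_bases	303936
design_total_bases	303788
design_coding_bases	89705
n_samples	10
total_snvs	1982
coding_snvs	488
unique_positions_total	579
in_target_genes	467
in_exons_incl_utr	266
in_introns	201
in_cds	149
in_non_coding	430
non_synonymous_in_cds	66
novel_non_synonymous	15
verified_novel	9
novel_recurrent	6
verified_novel_recurrent	2
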