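rank	consequence
1	transcript_ablation
2	splice_acceptor_variant
3	splice_donor_variant
4	stop_gained
5	frameshift_variant
6	stop_lost
7	start_lost
8	inframe_insertion
9	inframe_deletion
10	missense_variant
11	protein_altering_variant
12	splice_region_variant
13	incomplete_terminal_codon_variant
14	start_retained_variant
15	stop_retained_variant
16	synonymous_variant
17	coding_sequence_variant
18	5_prime_UTR_variant
19	3_prime_UTR_variant
20	non_coding_transcript_exon_variant
21	intron_variant
22	upstream_gene_variant
23	downstream_gene_variant
24	intergenic_variant
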