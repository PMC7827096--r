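rank	term	coding
1	transcript_ablation	1
2	splice_acceptor_variant	1
3	splice_donor_variant	1
4	stop_gained	1
5	frameshift_variant	1
6	stop_lost	1
7	start_lost	1
8	transcript_amplification	1
9	feature_elongation	0
10	feature_truncation	0
11	inframe_insertion	1
12	inframe_deletion	1
13	missense_variant	1
14	protein_altering_variant	1
15	splice_donor_5th_base_variant	0
16	splice_region_variant	0
17	splice_donor_region_variant	0
18	splice_polypyrimidine_tract_variant	0
19	incomplete_terminal_codon_variant	1
20	start_retained_variant	1
21	stop_retained_variant	1
22	synonymous_variant	1
23	coding_sequence_variant	1
24	mature_miRNA_variant	0
25	5_prime_UTR_variant	0
26	3_prime_UTR_variant	0
27	non_coding_transcript_exon_variant	0
28	intron_variant	0
29	NMD_transcript_variant	0
30	non_coding_transcript_variant	0
31	upstream_gene_variant	0
32	downstream_gene_variant	0
33	TFBS_ablation	0
34	TFBS_amplification	0
35	TF_binding_site_variant	0
36	regulatory_region_ablation	0
37	regulatory_region_amplification	0
38	regulatory_region_variant	0
39	intergenic_variant	0
40	sequence_variant	0
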