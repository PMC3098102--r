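# Published per-sample summaries of discarded-fragment reassignment by
# conserved gene adjacency: three whale-fall bone microbiome samples
# (assembled contigs) and 13 healthy Japanese gut microbiomes (unassembled
# singleton reads). n_discarded = fragments discarded by the original
# binning; n_reassigned = fragments the adjacency method assigned to a
# taxon; r_phylum / r_family = Pearson correlation between the
# composition profile of the reassigned fragments and the originally
# published profile at that rank.
sample	type	n_discarded	n_reassigned	r_phylum	r_family
whale_fall_1	contig	7039	1050	0.98	0.92
whale_fall_2	contig	7660	995	0.98	0.77
whale_fall_3	contig	4990	720	0.97	0.79
japanese_In-A	singleton	13399	3542	0.95	0.85
japanese_In-B	singleton	7078	2050	0.99	0.90
japanese_In-D	singleton	28244	5542	0.89	0.72
japanese_In-E	singleton	10838	2888	0.99	0.95
japanese_In-M	singleton	8546	2159	0.93	0.86
japanese_In-R	singleton	21661	3993	0.96	0.80
japanese_F1-S	singleton	15378	3216	0.95	0.82
japanese_F1-T	singleton	21780	4395	0.93	0.59
japanese_F1-U	singleton	11791	3711	0.99	0.99
japanese_F2-V	singleton	19733	4007	0.90	0.61
japanese_F2-W	singleton	16961	4011	0.89	0.77
japanese_F2-X	singleton	19351	4402	0.92	0.66
japanese_F2-Y	singleton	20061	4766	0.96	0.82
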