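# Published candidate-CDS count distributions of discarded singletons in
# three simulated benchmark communities of increasing complexity (low,
# moderate, high). n_cds bins reads by the number of partial coding
# sequences they contain: 0, 1, 2 or 3+ (three or more).
dataset	n_cds	count
simLC	0	2575
simLC	1	18219
simLC	2	17549
simLC	3+	3081
simMC	0	2637
simMC	1	18072
simMC	2	16832
simMC	3+	2838
simHC	0	3986
simHC	1	29926
simHC	2	27874
simHC	3+	4738
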