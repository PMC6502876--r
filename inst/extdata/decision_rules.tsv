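field	value	action	payload	provenance
quantity	relative	method	16S amplicon sequencing	stated
quantity	absolute	method	qPCR	stated
intent	compare_with_other_studies	guidance	use the identical primer pairs as the reference studies	stated
intent	characterize_dynamics	guidance	evaluate candidate primers with in-silico coverage analysis before use	stated
intent	characterize_dynamics	guidance	interpret temporal results relative to a reference sample from the same reactor	stated
degenerate_primers	FALSE	check	verify PCR product quality (single vs multiple bands) by gel electrophoresis	stated
any	any	check	run an in-silico coverage analysis for the chosen primer pair	stated
normalization_to_total_EUB	TRUE	warning	do not normalize measured group abundances to total eubacterial abundance; coverage differences between group and EUB primers make the quotient unreliable (false positives/negatives)	stated
question	presence	guidance	no branch-specific primer recommendation recorded	unspecified
question	richness	guidance	no branch-specific primer recommendation recorded	unspecified
question	evenness	guidance	no branch-specific primer recommendation recorded	unspecified
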