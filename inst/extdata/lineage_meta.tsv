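# Lineage metadata for the benchmark SRMSE table: variable-locus counts,
# full symmetric sample size (diploid individuals per population), and
# the F_ST of the full dataset. Published values.
lineage	variable_loci	full_size	fst
Clangula hyemalis	2442	7	0.004
Anas crecca	2481	6	0.020
Mareca penelope/americana	2315	8	0.044
Numenius phaeopus	2388	7	0.269
Tringa brevipes/incana	1636	8	0.585
Luscinia svecica	2516	7	0.014
Pinicola enucleator	2656	7	0.442
Pica pica/hudsonia	2199	7	0.328
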