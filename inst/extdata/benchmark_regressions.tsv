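# Published least-squares summaries of SRMSE on N accompanying the benchmark
# table: slope, intercept, r^2 and two-sided slope p-value; the m row was fit
# on the low-divergence lineages (F_ST < 0.05) only. The printed m slope is
# inconsistent with the table itself (see package documentation).
parameter	group	slope	intercept	r_squared	p_value
m	low	-0.00858	0.87714	0.413	0.0007
nu1	all	-0.17563	1.05063	0.117	0.0156
nu2	all	-0.16171	0.97351	0.305	0.00004
T	all	-0.10045	0.70147	0.237	0.0004
theta	all	-0.03825	0.34738	0.220	0.0007
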