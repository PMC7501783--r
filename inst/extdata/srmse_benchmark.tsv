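# Benchmark SRMSE table: scaled root mean square error of split-migration
# parameter estimates at diminished symmetric sample sizes (N diploid
# individuals per population), for eight pairwise trans-Beringian bird
# lineage datasets (UCE loci, one SNP per locus). Published values.
lineage	parameter	N	srmse
Clangula hyemalis	m	6	0.391
Clangula hyemalis	m	5	0.438
Clangula hyemalis	m	4	0.451
Clangula hyemalis	m	3	0.436
Clangula hyemalis	m	2	0.540
Clangula hyemalis	m	1	0.500
Anas crecca	m	5	0.262
Anas crecca	m	4	0.556
Anas crecca	m	3	0.803
Anas crecca	m	2	1.123
Anas crecca	m	1	0.942
Mareca penelope/americana	m	7	0.624
Mareca penelope/americana	m	6	0.187
Mareca penelope/americana	m	5	0.221
Mareca penelope/americana	m	4	0.339
Mareca penelope/americana	m	3	0.661
Mareca penelope/americana	m	2	0.838
Mareca penelope/americana	m	1	0.913
Numenius phaeopus	m	6	0.082
Numenius phaeopus	m	5	0.128
Numenius phaeopus	m	4	0.330
Numenius phaeopus	m	3	0.627
Numenius phaeopus	m	2	2.026
Numenius phaeopus	m	1	0.753
Tringa brevipes/incana	m	7	1.293
Tringa brevipes/incana	m	6	1.213
Tringa brevipes/incana	m	5	1.214
Tringa brevipes/incana	m	4	1.081
Tringa brevipes/incana	m	3	0.928
Tringa brevipes/incana	m	2	1.659
Tringa brevipes/incana	m	1	0.992
Luscinia svecica	m	6	0.262
Luscinia svecica	m	5	0.570
Luscinia svecica	m	4	0.747
Luscinia svecica	m	3	0.642
Luscinia svecica	m	2	0.699
Luscinia svecica	m	1	0.619
Pinicola enucleator	m	6	2.809
Pinicola enucleator	m	5	2.779
Pinicola enucleator	m	4	5.003
Pinicola enucleator	m	3	11.108
Pinicola enucleator	m	2	38.261
Pinicola enucleator	m	1	0.486
Pica pica/hudsonia	m	6	0.650
Pica pica/hudsonia	m	5	0.771
Pica pica/hudsonia	m	4	1.459
Pica pica/hudsonia	m	3	2.182
Pica pica/hudsonia	m	2	5.303
Pica pica/hudsonia	m	1	1.053
Clangula hyemalis	nu1	6	0.225
Clangula hyemalis	nu1	5	0.156
Clangula hyemalis	nu1	4	0.174
Clangula hyemalis	nu1	3	0.122
Clangula hyemalis	nu1	2	0.156
Clangula hyemalis	nu1	1	0.432
Anas crecca	nu1	5	0.081
Anas crecca	nu1	4	0.136
Anas crecca	nu1	3	0.214
Anas crecca	nu1	2	0.195
Anas crecca	nu1	1	0.384
Mareca penelope/americana	nu1	7	0.073
Mareca penelope/americana	nu1	6	0.161
Mareca penelope/americana	nu1	5	0.106
Mareca penelope/americana	nu1	4	0.130
Mareca penelope/americana	nu1	3	0.183
Mareca penelope/americana	nu1	2	0.224
Mareca penelope/americana	nu1	1	0.329
Numenius phaeopus	nu1	6	0.049
Numenius phaeopus	nu1	5	0.069
Numenius phaeopus	nu1	4	0.109
Numenius phaeopus	nu1	3	0.163
Numenius phaeopus	nu1	2	0.299
Numenius phaeopus	nu1	1	0.318
Tringa brevipes/incana	nu1	7	0.116
Tringa brevipes/incana	nu1	6	0.109
Tringa brevipes/incana	nu1	5	0.178
Tringa brevipes/incana	nu1	4	0.282
Tringa brevipes/incana	nu1	3	0.512
Tringa brevipes/incana	nu1	2	1.788
Tringa brevipes/incana	nu1	1	6.511
Luscinia svecica	nu1	6	0.112
Luscinia svecica	nu1	5	0.398
Luscinia svecica	nu1	4	0.459
Luscinia svecica	nu1	3	0.496
Luscinia svecica	nu1	2	0.541
Luscinia svecica	nu1	1	0.464
Pinicola enucleator	nu1	6	0.141
Pinicola enucleator	nu1	5	0.167
Pinicola enucleator	nu1	4	0.275
Pinicola enucleator	nu1	3	0.307
Pinicola enucleator	nu1	2	0.505
Pinicola enucleator	nu1	1	0.427
Pica pica/hudsonia	nu1	6	0.157
Pica pica/hudsonia	nu1	5	0.202
Pica pica/hudsonia	nu1	4	0.271
Pica pica/hudsonia	nu1	3	0.296
Pica pica/hudsonia	nu1	2	0.462
Pica pica/hudsonia	nu1	1	0.907
Clangula hyemalis	nu2	6	0.141
Clangula hyemalis	nu2	5	0.164
Clangula hyemalis	nu2	4	0.193
Clangula hyemalis	nu2	3	0.156
Clangula hyemalis	nu2	2	0.170
Clangula hyemalis	nu2	1	0.261
Anas crecca	nu2	5	0.138
Anas crecca	nu2	4	0.146
Anas crecca	nu2	3	0.150
Anas crecca	nu2	2	0.354
Anas crecca	nu2	1	0.635
Mareca penelope/americana	nu2	7	0.069
Mareca penelope/americana	nu2	6	0.091
Mareca penelope/americana	nu2	5	0.135
Mareca penelope/americana	nu2	4	0.151
Mareca penelope/americana	nu2	3	0.217
Mareca penelope/americana	nu2	2	0.320
Mareca penelope/americana	nu2	1	1.588
Numenius phaeopus	nu2	6	0.059
Numenius phaeopus	nu2	5	0.061
Numenius phaeopus	nu2	4	0.122
Numenius phaeopus	nu2	3	0.198
Numenius phaeopus	nu2	2	0.345
Numenius phaeopus	nu2	1	0.554
Tringa brevipes/incana	nu2	7	0.154
Tringa brevipes/incana	nu2	6	0.133
Tringa brevipes/incana	nu2	5	0.168
Tringa brevipes/incana	nu2	4	0.204
Tringa brevipes/incana	nu2	3	0.228
Tringa brevipes/incana	nu2	2	0.887
Tringa brevipes/incana	nu2	1	3.241
Luscinia svecica	nu2	6	0.106
Luscinia svecica	nu2	5	0.285
Luscinia svecica	nu2	4	0.477
Luscinia svecica	nu2	3	0.507
Luscinia svecica	nu2	2	0.635
Luscinia svecica	nu2	1	0.557
Pinicola enucleator	nu2	6	0.094
Pinicola enucleator	nu2	5	0.109
Pinicola enucleator	nu2	4	0.210
Pinicola enucleator	nu2	3	0.332
Pinicola enucleator	nu2	2	0.537
Pinicola enucleator	nu2	1	0.526
Pica pica/hudsonia	nu2	6	0.182
Pica pica/hudsonia	nu2	5	0.282
Pica pica/hudsonia	nu2	4	0.308
Pica pica/hudsonia	nu2	3	0.391
Pica pica/hudsonia	nu2	2	0.566
Pica pica/hudsonia	nu2	1	1.702
Clangula hyemalis	T	6	0.329
Clangula hyemalis	T	5	0.310
Clangula hyemalis	T	4	0.358
Clangula hyemalis	T	3	0.282
Clangula hyemalis	T	2	0.434
Clangula hyemalis	T	1	0.632
Anas crecca	T	5	0.095
Anas crecca	T	4	0.128
Anas crecca	T	3	0.213
Anas crecca	T	2	0.207
Anas crecca	T	1	0.369
Mareca penelope/americana	T	7	0.100
Mareca penelope/americana	T	6	0.153
Mareca penelope/americana	T	5	0.097
Mareca penelope/americana	T	4	0.111
Mareca penelope/americana	T	3	0.164
Mareca penelope/americana	T	2	0.194
Mareca penelope/americana	T	1	0.315
Numenius phaeopus	T	6	0.052
Numenius phaeopus	T	5	0.066
Numenius phaeopus	T	4	0.110
Numenius phaeopus	T	3	0.196
Numenius phaeopus	T	2	0.350
Numenius phaeopus	T	1	0.322
Tringa brevipes/incana	T	7	0.138
Tringa brevipes/incana	T	6	0.149
Tringa brevipes/incana	T	5	0.208
Tringa brevipes/incana	T	4	0.261
Tringa brevipes/incana	T	3	0.275
Tringa brevipes/incana	T	2	1.006
Tringa brevipes/incana	T	1	2.508
Luscinia svecica	T	6	0.056
Luscinia svecica	T	5	0.118
Luscinia svecica	T	4	0.250
Luscinia svecica	T	3	0.178
Luscinia svecica	T	2	0.284
Luscinia svecica	T	1	0.408
Pinicola enucleator	T	6	0.183
Pinicola enucleator	T	5	0.291
Pinicola enucleator	T	4	0.437
Pinicola enucleator	T	3	0.578
Pinicola enucleator	T	2	0.848
Pinicola enucleator	T	1	0.396
Pica pica/hudsonia	T	6	0.193
Pica pica/hudsonia	T	5	0.265
Pica pica/hudsonia	T	4	0.350
Pica pica/hudsonia	T	3	0.444
Pica pica/hudsonia	T	2	0.608
Pica pica/hudsonia	T	1	0.673
Clangula hyemalis	theta	6	0.262
Clangula hyemalis	theta	5	0.295
Clangula hyemalis	theta	4	0.296
Clangula hyemalis	theta	3	0.264
Clangula hyemalis	theta	2	0.333
Clangula hyemalis	theta	1	0.490
Anas crecca	theta	5	0.077
Anas crecca	theta	4	0.094
Anas crecca	theta	3	0.153
Anas crecca	theta	2	0.126
Anas crecca	theta	1	0.237
Mareca penelope/americana	theta	7	0.068
Mareca penelope/americana	theta	6	0.046
Mareca penelope/americana	theta	5	0.052
Mareca penelope/americana	theta	4	0.059
Mareca penelope/americana	theta	3	0.083
Mareca penelope/americana	theta	2	0.094
Mareca penelope/americana	theta	1	0.153
Numenius phaeopus	theta	6	0.035
Numenius phaeopus	theta	5	0.042
Numenius phaeopus	theta	4	0.067
Numenius phaeopus	theta	3	0.113
Numenius phaeopus	theta	2	0.173
Numenius phaeopus	theta	1	0.231
Tringa brevipes/incana	theta	7	0.337
Tringa brevipes/incana	theta	6	0.283
Tringa brevipes/incana	theta	5	0.280
Tringa brevipes/incana	theta	4	0.338
Tringa brevipes/incana	theta	3	0.395
Tringa brevipes/incana	theta	2	0.608
Tringa brevipes/incana	theta	1	0.670
Luscinia svecica	theta	6	0.030
Luscinia svecica	theta	5	0.070
Luscinia svecica	theta	4	0.158
Luscinia svecica	theta	3	0.108
Luscinia svecica	theta	2	0.126
Luscinia svecica	theta	1	0.242
Pinicola enucleator	theta	6	0.060
Pinicola enucleator	theta	5	0.118
Pinicola enucleator	theta	4	0.186
Pinicola enucleator	theta	3	0.224
Pinicola enucleator	theta	2	0.284
Pinicola enucleator	theta	1	0.298
Pica pica/hudsonia	theta	6	0.123
Pica pica/hudsonia	theta	5	0.161
Pica pica/hudsonia	theta	4	0.218
Pica pica/hudsonia	theta	3	0.278
Pica pica/hudsonia	theta	2	0.386
Pica pica/hudsonia	theta	1	0.463
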