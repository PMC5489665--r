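rank	boxplot_gene	whisker_d	genorm_gene	genorm_m	normfinder_gene	normfinder_stability
1	CaREV16	0.951	CaREV05	0	CaREV16	0.192
2	CaREV21	0.990	CaREV08	0	CaREV21	0.357
3	CaREV27	1.107	CaREV31	0.097	CaREV27	0.446
4	CaREV24	1.443	CaREV33	0.230	CaREV26	0.482
5	CaREV09	1.592	CaREV09	0.323	CaREV14	0.497
6	CaREV28	2.023	CaREV27	0.402	CaREV23	0.580
7	CaREV33	2.371	CaREV21	0.449	CaREV19	0.582
8	CaREV31	2.426	CaREV16	0.553	CaREV28	0.583
9	CaREV05	2.552	CaREV28	0.640	CaREV09	0.634
10	CaREV08	2.552	CaREV23	0.776	CaREV20	0.678
11	CaREV23	2.572	CaREV26	0.859	CaREV25	0.697
12	CaREV32	2.586	CaREV32	0.910	CaREV32	0.699
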