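gene	efficiency	r_squared	mean_ct
CaREV01	0.91	0.992	NA
CaREV02	NA	NA	32.27
CaREV03	0.91	0.996	NA
CaREV04	NA	NA	32.45
CaREV05	1.05	0.997	NA
CaREV06	0.89	1	NA
CaREV07	0.84	0.923	NA
CaREV08	NA	NA	NA
CaREV09	0.96	0.999	NA
CaREV10	1.7	0.994	31.36
CaREV11	1.06	0.978	29.08
CaREV12	0.94	0.982	NA
CaREV13	0.84	0.999	NA
CaREV14	0.92	0.997	NA
CaREV15	0.99	0.995	NA
CaREV16	1.03	0.989	NA
CaREV17	0.9	0.941	NA
CaREV18	0.71	0.994	21.71
CaREV19	0.98	0.997	NA
CaREV20	0.95	0.998	NA
CaREV21	0.97	0.996	NA
CaREV22	0.97	0.996	NA
CaREV23	0.99	0.999	28.4
CaREV24	0.94	0.998	NA
CaREV25	1.06	0.992	NA
CaREV26	0.98	0.991	NA
CaREV27	0.99	0.997	NA
CaREV28	0.86	1	NA
CaREV29	0.86	1	NA
CaREV30	0.87	0.998	NA
CaREV31	0.73	0.989	NA
CaREV32	0.93	0.999	NA
CaREV33	0.79	0.999	NA
CaREV34	0.83	0.999	NA
CaREV35	0.8	0.995	NA
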