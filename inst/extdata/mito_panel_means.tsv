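gene	probe	mean_a	se_a	mean_b	se_b
Mt-coxII	1	15.19	0.09	14.80	0.20
Mt-coxII	2	14.84	0.09	14.45	0.21
Mt-coxIII	1	15.78	0.10	15.71	0.03
Mt-atp6	1	14.76	0.04	14.42	0.23
Mt-atp6	2	15.75	0.10	15.79	0.03
Mt-atp8	1	15.48	0.05	15.21	0.15
Mt-cytB	1	15.66	0.08	15.59	0.08
Mt-cytB	2	15.87	0.05	15.73	0.04
Mt-nd1	1	15.51	0.06	15.24	0.13
Mt-nd1	2	15.93	0.09	15.93	0.01
Mt-nd2	1	14.73	0.06	14.29	0.19
Mt-nd3	1	8.45	0.17	8.16	0.23
Mt-nd4	1	15.90	0.06	15.84	0.05
Mt-nd4	2	15.66	0.07	15.54	0.10
Mt-nd4l	1	12.76	0.16	12.28	0.29
Mt-nd4l	2	11.37	0.13	10.98	0.37
Mt-nd5	1	12.52	0.05	12.23	0.25
Mt-nd6	1	7.92	0.37	7.72	0.23
Mt-nd5	2	7.94	0.07	7.74	0.17
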