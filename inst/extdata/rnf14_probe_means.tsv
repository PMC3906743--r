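probe_id	mean_variant3	se_variant3	mean_variant1	se_variant1	mean_control	se_control
ILMN_2675078	10.54	0.11	9.02	0.10	8.78	0.13
ILMN_2682811	7.44	0.13	7.65	0.13	7.53	0.14
ILMN_2868579	12.73	0.17	12.72	0.17	12.73	0.08
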