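primer	treatment	lsm	censored
all_species	control	24.99	FALSE
all_species	variant3	20.17	FALSE
all_species	variant1	24.89	FALSE
endogenous	control	26.59	FALSE
endogenous	variant3	26.73	FALSE
endogenous	variant1	26.92	FALSE
v3_construct	control	31.93	TRUE
v3_construct	variant3	19.41	FALSE
v3_construct	variant1	30.32	TRUE
v1_construct	control	35.60	TRUE
v1_construct	variant3	34.19	TRUE
v1_construct	variant1	29.19	FALSE
actb	control	23.16	FALSE
actb	variant3	23.36	FALSE
actb	variant1	23.10	FALSE
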