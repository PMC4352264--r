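pair	chr_a	chr_b	ks	ka	ratio	selection	dup_type	t_mya
PvC3H29/39	Chr5a	Chr5b	0.000	0.041	NA	Diversifying	Homeologous	NA
PvC3H34/45	Chr5a	Chr5b	0.000	0.036	NA	Diversifying	Homeologous	NA
PvC3H62/66	Chr9a	Chr9b	0.000	0.018	NA	Diversifying	Homeologous	NA
PvC3H54/57	Chr7a	Chr7b	0.039	0.052	1.316	Diversifying	Homeologous	3
PvC3H33/41	Chr5a	Chr5b	0.041	0.019	0.459	Purifying	Homeologous	3.1
PvC3H6/7	Chr1a	Chr1b	0.046	0.075	1.649	Diversifying	Homeologous	3.5
PvC3H61/65	Chr9a	Chr9b	0.047	0.030	0.638	Purifying	Homeologous	3.6
PvC3H32/42	Chr5a	Chr5b	0.060	0.006	0.104	Purifying	Homeologous	4.6
PvC3H35/44	Chr5a	Chr5b	0.065	0.044	0.672	Purifying	Homeologous	5
PvC3H1/9	Chr1a	Chr1b	0.073	0.061	0.841	Purifying	Homeologous	5.6
PvC3H31/43	Chr5a	Chr5b	0.076	0.066	0.874	Purifying	Homeologous	5.8
PvC3H10/15	Chr2a	Chr2b	0.082	0.092	1.119	Diversifying	Homeologous	6.3
PvC3H30/40	Chr5a	Chr5b	0.102	0.084	0.825	Purifying	Homeologous	7.9
PvC3H20/23	Chr3a	Chr3b	0.131	0.064	0.489	Purifying	Homeologous	10.1
PvC3H46/51	Chr6a	Chr6b	0.151	0.013	0.087	Purifying	Homeologous	11.6
PvC3H5/6	Chr1a	Chr1a	0.163	0.060	0.367	Purifying	Tandem	12.5
PvC3H17/50	Chr3a	Chr6b	0.237	0.030	0.128	Purifying	Paralogous	18.2
PvC3H32/33	Chr5a	Chr5a	0.282	0.444	1.575	Diversifying	Tandem	21.7
PvC3H41/42	Chr5b	Chr5b	0.287	0.464	1.616	Diversifying	Tandem	22.1
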