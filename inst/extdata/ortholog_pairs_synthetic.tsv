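gene_a	chr_a	start_a	end_a	gene_b	chr_b	start_b	end_b	species_a	species_b
synw01	7B	674.1998	674.2018	synr01	6	3.1052	3.1072	wheat	rice
synw02	3B	828.5927	828.5947	synr02	1	25.0476	25.0496	wheat	rice
synw03	4D	459.6863	459.6883	synr03	3	14.6816	14.6836	wheat	rice
synw04	5A	700.178	700.18	synr04	11	10.4763	10.4783	wheat	rice
synw05	1B	27.1501	27.1521	synm05	1	224.7217	224.7237	wheat	maize
synw06	2A	82.1864	82.1884	synm06	5	19.224	19.226	wheat	maize
synw07	4A	647.0905	647.0925	synm07	1	275.0245	275.0265	wheat	maize
synw08	4B	649.4725	649.4745	synm08	8	47.1479	47.1499	wheat	maize
synw09	4B	518.0975	518.0995	synm09	2	122.6773	122.6793	wheat	maize
synw10	7B	576.0474	576.0494	synr10	6	29.185	29.187	wheat	rice
synw11	7B	575.6535	575.6555	synm11	5	57.016	57.018	wheat	maize
synw12	7B	573.9667	573.9687	synm12	6	90.122	90.124	wheat	maize
synw13	4B	627.7289	627.7309	synr13	3	2.0438	2.0458	wheat	rice
synw14	7B	741.5711	741.5731	synr14	10	13.3614	13.3634	wheat	rice
synw15	3D	33.2955	33.2975	synm15	10	69.4842	69.4862	wheat	maize
synw16	2A	88.2962	88.2982	synr16	7	7.396	7.398	wheat	rice
synw17	4D	484.6861	484.6881	synr17	6	21.3982	21.4002	wheat	rice
synw18	4D	461.4914	461.4934	synr18	7	20.0286	20.0306	wheat	rice
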