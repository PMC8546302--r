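snp	chrom	mb	trait	study
AX_109881378	3B	21.25	GY	Li_2019
M8680	4A	157.56	GY	Mathew_2019
AX-110458478	5A	692.17	GY	Hu_2020
AX-108839508	5A	692.16	GY	Hu_2020
AX-109388349	5A	692.18	GY	Hu_2020
AX-108829895	5A	692.39	GY	Hu_2020
S7B_687521301	7B	687.52	NG	Jamil_2019
AX-95235641	4D	442.17	PH	Hu_2020
AX-110149206	7B	676.25	PH	Hu_2020
AX-95658823	7B	675.28	PH	Hu_2020
AX-95149761	7B	680.08	PH	Hu_2020
AX-109901032	1B	566.19	SL	Li_2019
AX-109394807	7A	29.32	SL	Hu_2020
AX-109066809	4A	179.94	SN	Li_2019
AX-111551006	2B	706.93	SNS	Li_2019
AX-169338181	4D	433.00	SNS	Li_2019
AX-111020167	4D	471.23	SNS	Li_2019
AX-111542213	7A	4.55	SNS	Li_2019
S4A_733664972	4A	733.66	TKW	Jamil_2019
AX-111600193	4A	642.37	TKW	Li_2019
AX-94402252	4B	564.39	TKW	Hu_2020
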