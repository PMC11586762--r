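category	characteristic	n_misc	pct_misc	n_btnl8	pct_btnl8	n_iei	pct_iei
group_size	total	154	100	9	100	6	100
demographics	sex_male	88	57.1	4	44.4	6	100
demographics	comorbidities	51	33.1	2	22.2	2	33.3
ancestry	AMR	45	29.2	2	22.2	1	16.7
ancestry	AFR	41	26.6	3	33.3	3	50
ancestry	EUR	40	26.0	3	33.3	1	16.7
ancestry	SAS	18	11.7	1	11.1	0	0
ancestry	EAS	5	3.2	0	0	1	16.7
ancestry	Unknown	5	3.2	0	0	0	0
sars_cov_2	pcr_positive	21	13.6	1	11.1	0	0
sars_cov_2	serology_positive	125	81.2	6	66.7	6	100
sars_cov_2	serology_unknown	13	8.4	2	22.2	0	0
symptoms	fever	154	100	9	100	6	100
symptoms	gastrointestinal	122	79.2	9	100	6	100
symptoms	conjunctivitis	99	64.3	8	88.9	5	83.3
symptoms	rash	87	56.5	6	66.7	5	83.3
symptoms	systemic_shock	46	29.9	4	44.4	2	33.3
symptoms	cardiovascular	45	29.2	2	22.2	1	16.7
symptoms	lymphadenopathy	26	16.9	1	11.1	0	0
symptoms	inflamed_extremities	21	13.6	2	22.2	2	33.3
symptoms	respiratory	16	10.4	0	0	0	0
symptoms	mucositis	14	9.1	0	0	0	0
severity	icu	98	63.6	5	55.6	4	66.7
severity	death	1	0.6	0	0	0	0
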