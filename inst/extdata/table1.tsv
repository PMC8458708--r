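study_id	year	tumor_type	phase	line	intervention	n	orr_pct	dcr_pct	mpfs_mo
Motzer 2021	2021	RCC	III	1L	L + K	355	71.0	90.2	23.9
Chung 2021	2021	GC	II	3L	L + K	31	10.0	48.0	2.5
Villanueva 2021	2021	CHOL	II	2L	L + K	31	10.0	68.0	6.1
Gomez-Roca 2021	2021	COAD	II	3L	L + K	32	22.0	47.0	2.3
Lee 2020	2020	RCC	II	>=2L	L + K	104	51.0	91.0	11.7
Kawazoe 2020	2020	GC	II	1/2L	L + K	29	69.0	100.0	7.1
Haugen 2020	2020	THCA	II	>=2L	L + K	30	62.0	97.0	
Makker 2020	2020	UCEC	Ib/II	>=2L	L + K	94	38.3	78.7	7.4
Taylor 2020 SKCM	2020	SKCM	Ib/II	>=2L	L + K	21	48.0	81.0	5.5
Arance 2020	2020	SKCM	Ib/II	>=2L	L + K	103	21.4	65.0	4.2
Finn 2020	2020	LIHC	Ib	1L	L + K	104	46.0	88.0	9.3
Li 2020	2020	LIHC	NE	1L	L + PD-1 inhibitors	22	50.0	90.9	12.1
Kudo 2020	2020	LIHC	Ib	1L	L + O	24	66.7	91.7	7.4
Taylor 2020 HNSC	2020	HNSC	Ib/II	>=2L	L + K	22	46.0	91.0	4.7
Taylor 2020 NSCLC	2020	NSCLC	Ib/II	>=2L	L + K	21	33.0	81.0	5.9
Lwin 2020 OV	2020	OV	II	4L	L + K	31	32.3	74.2	
Lwin 2020 TNBC	2020	TNBC	II	2/3L	L + K	31	29.0	58.1	
Lin 2020	2020	CHOL	NE	>=2L	L + K	32	25.0	78.1	4.9
Taylor 2020 BLCA	2020	BLCA	Ib/II	>=2L	L + K	20	25.0	70.0	5.4
Lwin 2020 GBM	2020	GBM	II	2L	L + K	31	16.1	58.1	
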