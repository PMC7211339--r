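rank	symbol	display_name	betweenness
1	CACNA1C	Calcium voltage-gated channel subunit alpha1 C	0.338153
2	GRIA1	Glutamate ionotropic receptor AMPA-type subunit 1	0.1574122
3	DRD2	Dopamine receptor D2	0.1136524
4	NOS1	Nitric oxide synthase 1	0.0903783
5	SLC18A1	Solute carrier family 18 member A1	0.0661232
6	HTR2A	5-Hydroxytryptamine receptor 2A	0.0660831
7	DRD1	Dopamine receptor D1	0.0500920
8	GRIK2	Glutamate ionotropic receptor kainate-type subunit 2	0.0481045
9	DRD5	Dopamine receptor D5	0.0458659
10	HTR1A	5-Hydroxytryptamine receptor 1A, serotonin receptor	0.0443705
11	GRIN2B	Glutamate ionotropic receptor NMDA-type subunit 2B	0.036738
12	SLC6A4	Solute carrier family 6 member 4	0.020317
13	GRIK3	Glutamate ionotropic receptor kainate-type subunit 3	0.038491
14	DRD3	Dopamine receptor D3	0.017168
15	CNR1	Cannabinoid receptor 1	0.007217
16	ADRA1A	Adrenoceptor alpha 1A	0.006255
17	BDNF	Brain-derived neurotrophic factor	0.005617
18	TPH2	Tryptophan hydroxylase 2	0.0045508
19	DRD4	Dopamine receptor D4	0.004232
20	GAD1	Glutamate decarboxylase 1	0.003155
21	GABRA1	Gamma-aminobutyric acid type A receptor alpha1 subunit	0.001786
22	NTRK2	Neurotrophic receptor tyrosine kinase 2	0.001023
23	ACE	Angiotensin I converting enzyme	0
24	ATXN1	Ataxin 1	0
25	CHRNA7	Cholinergic receptor nicotinic alpha 7 subunit	0
26	CRHR2	Corticotropin-releasing hormone receptor 2	0
27	DBH	Dopamine beta-hydroxylase	0
28	EFNA5	Ephrin A5	0
29	GAD2	Glutamic acid decarboxylase 2	0
30	GRIN2A	Glutamate ionotropic receptor NMDA-type subunit 2A	0
31	HTR2C	5-Hydroxytryptamine receptor 2C	0
32	HTR3A	5-Hydroxytryptamine receptor 3A	0
33	OLFM1	Olfactomedin 1	0
34	TNF	Tumor necrosis factor	0
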