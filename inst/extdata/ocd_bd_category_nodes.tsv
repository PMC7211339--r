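category_type	category_id	name	fdr	betweenness
pathway	hsa04728	Dopaminergic synapse	3.86e-08	0.13604918
pathway	hsa04024	cAMP signaling pathway	1.19e-06	0.12989786
pathway	hsa04726	Serotonergic synapse	0.000112	0.0838125
pathway	hsa04020	Calcium signaling pathway	0.000979	0.07812904
pathway	hsa04724	Glutamatergic synapse	0.001158	0.04450784
pathway	hsa04727	GABAergic synapse	0.005543	0.03118593
pathway	hsa04723	Retrograde endocannabinoid signaling	0.00753	0.04801305
molecular_function	GO:0035240	Dopamine binding	3.59e-10	0.011851
molecular_function	GO:0001588	Dopamine neurotransmitter receptor activity, coupled via Gs	9.72e-09	0.0047987
molecular_function	GO:0005234	Extracellular-glutamate-gated ion channel activity	2.06e-06	0
molecular_function	GO:0008227	G-protein-coupled amine receptor activity	0.000142	0.00705387
molecular_function	GO:0016597	Amino acid binding	0.000211	0.02687112
molecular_function	GO:0015277	Kainate-selective glutamate receptor activity	0.001517	0
molecular_function	GO:0008504	Monoamine transmembrane transporter activity	0.004829	0.00237254
molecular_function	GO:0051378	Serotonin binding	0.004829	5.53e-04
molecular_function	GO:0008519	Ammonium transmembrane transporter activity	0.028746	0.00237254
molecular_function	GO:0099589	Serotonin receptor activity	0.028746	5.53e-04
cellular_component	GO:0030425	Dendrite	0.000151	0.07980464
cellular_component	GO:0033267	Axon part	0.000215	0.03089599
cellular_component	GO:0014069	Postsynaptic density	0.000243	0.05051219
cellular_component	GO:0008328	Ionotropic glutamate receptor complex	0.001148	0.0055914
cellular_component	GO:0045121	Membrane raft	0.001158	0.05504978
cellular_component	GO:0034703	Cation channel complex	0.003335	0.02751275
cellular_component	GO:0043204	Perikaryon	0.01023	0.00847745
cellular_component	GO:0008021	Synaptic vesicle	0.013692	0.01103456
brain_region	cortex	Cortex	0.008	0.22937063
brain_region	striatum	Striatum	0.008	0.1299988
brain_region	hippocampus	Hippocampus	0.008	0.07421981
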