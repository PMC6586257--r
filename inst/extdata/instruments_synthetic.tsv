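rsid	effect_allele	other_allele	eaf	beta_serum_iron	se_serum_iron	beta_log10_ferritin	se_log10_ferritin	beta_transferrin	se_transferrin	beta_transferrin_saturation	se_transferrin_saturation
rs1800562	A	G	0.07	0.32	0.016	0.176	0.016	-0.208	0.016	0.272	0.016
rs1799945	G	C	0.15	0.19	0.011	0.1045	0.011	-0.1235	0.011	0.1615	0.011
rs855791	G	A	0.45	0.18	0.008	0.099	0.008	-0.117	0.008	0.153	0.008
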