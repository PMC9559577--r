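CXCR_chemokine_receptor_binding	chemokine ligands binding CXCR-family receptors	CXCL1	CXCL2	CXCL5	CXCL8
chemokine_activity	molecules with chemokine activity	CXCL1	CXCL2	CXCL3	CXCL5	CXCL6	CXCL8	CXCL9	CXCL10	CXCL11	CXCL12	CXCL13	CXCL14	CCL2	CCL5	CCL20	PPBP	PF4
peptidoglycan_binding	molecules binding bacterial peptidoglycan	REG3G	REG3A	ZG16
oligosaccharide_binding	molecules binding oligosaccharides	REG3G	REG3A	ITLN1
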