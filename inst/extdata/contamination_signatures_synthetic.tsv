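# Blood-cell contamination panels for plasma/serum proteome QC.
# Membership beyond the literature-named driver proteins is a curated
# synthetic stand-in for externally published erythrocyte/platelet/
# coagulation panels; replace via loadSignatures() when panel data are
# available. Positive weight = protein increases under contamination.
signature	feature_id	weight	source	provenance
erythrocyte	CAT	1	contamination	synthetic curated panel; driver
erythrocyte	CA2	1	contamination	synthetic curated panel; driver
erythrocyte	CA1	1	contamination	synthetic curated panel
erythrocyte	BLVRB	1	contamination	synthetic curated panel; driver
erythrocyte	PRDX2	1	contamination	synthetic curated panel; driver
erythrocyte	PRDX1	1	contamination	synthetic curated panel
erythrocyte	ALDOA	1	contamination	synthetic curated panel; driver
erythrocyte	HBB	1	contamination	synthetic curated panel
erythrocyte	HBA1	1	contamination	synthetic curated panel
erythrocyte	HBD	1	contamination	synthetic curated panel
erythrocyte	SLC4A1	1	contamination	synthetic curated panel
erythrocyte	BPGM	1	contamination	synthetic curated panel
platelet	PF4	1	contamination	synthetic curated panel
platelet	TLN1	1	contamination	synthetic curated panel
platelet	MYH9	1	contamination	synthetic curated panel
platelet	FLNA	1	contamination	synthetic curated panel
platelet	ITGA2B	1	contamination	synthetic curated panel
platelet	GP1BA	1	contamination	synthetic curated panel
platelet	VCL	1	contamination	synthetic curated panel
platelet	TUBB1	1	contamination	synthetic curated panel
platelet	ACTN1	1	contamination	synthetic curated panel
platelet	TREML1	1	contamination	synthetic curated panel
platelet	SELP	1	contamination	synthetic curated panel
platelet	MMRN1	1	contamination	synthetic curated panel
coagulation	PPBP	1.0	contamination	synthetic curated panel; driver
coagulation	THBS1	0.8	contamination	synthetic curated panel; driver
coagulation	F13A1	-1.0	contamination	synthetic curated panel; driver
coagulation	FGA	-0.9	contamination	synthetic curated panel
coagulation	FGB	-0.9	contamination	synthetic curated panel
coagulation	FGG	-0.9	contamination	synthetic curated panel
coagulation	F2	-0.5	contamination	synthetic curated panel
coagulation	PROS1	-0.4	contamination	synthetic curated panel
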