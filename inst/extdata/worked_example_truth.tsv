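gene_id	class	note
boundary_rpkm	low_expression	RPKM exactly 3 at wt 36 hpf: excluded by the expression floor
above_rpkm	unregulated	RPKM 3.01: retained (floor is a strict inequality)
boundary_enrich	unregulated	DP/GFP-only ratio exactly 1.5: retained (inclusive)
below_enrich	enrichment_excluded	DP/GFP-only ratio 6/4.1 < 1.5: excluded
contam_gfp	contaminant_gfp	GFP-only contaminant, excluded by the enrichment ratio
contam_dsred	contaminant_dsred	DsRed-only contaminant, excluded by the enrichment ratio
notch_inh_1	notch_inhibited	strong Notch-inhibited responder
notch_act_1	notch_activated	strong Notch-activated responder
boundary_act	notch_activated	OE-fc/mut-fc exactly 1.5: activated (inclusive)
boundary_inh	notch_inhibited	OE-fc/mut-fc exactly 0.667: inhibited (inclusive)
boundary_dbz_up	notch_activated	NICD-fc/DBZ-fc exactly 1.25: survives refinement
boundary_dbz	notch_inhibited	NICD-fc/DBZ-fc exactly 0.8: survives refinement
dbz_removed_act	unregulated	activated pre-DBZ, NICD/DBZ 1.176 < 1.25: removed
dbz_removed_inh	unregulated	inhibited pre-DBZ, NICD/DBZ 0.833 > 0.8: removed
edn1_inh_1	edn1_inhibited	strong Edn1-inhibited responder
edn1_act_1	edn1_activated	strong Edn1-activated responder
co_pos_1	co_regulated_positive	activated by both pathways
co_neg_1	co_regulated_negative	inhibited by both pathways
antag_induced	antagonistic_pair	Notch-inhibited + Edn1-activated, 12x induced 20->28 hpf
zero_at_20	unregulated	zero RPKM at 20 hpf: temporal ratio uses the 0.01 replacement
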