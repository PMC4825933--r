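gene_id	wt_dp_20	wt_gfp_20	wt_dsred_20	wt_dp_28	wt_gfp_28	wt_dsred_28	wt_dp_36	wt_gfp_36	wt_dsred_36	edn1_mut_36	edn1_ctrl_36	jag1b_mut_36	jag1b_ctrl_36	edn1_oe_36	nicd_oe_36	hs_ctrl_36	dbz_36	vehicle_ctrl_36
boundary_rpkm	100	10	10	100	10	10	3	0.5	0.5	100	100	100	100	100	100	100	100	100
above_rpkm	100	10	10	100	10	10	3.0099999999999998	1	1	100	100	100	100	100	100	100	100	100
boundary_enrich	100	10	10	100	10	10	6	4	1	100	100	100	100	100	100	100	100	100
below_enrich	100	10	10	100	10	10	6	4.0999999999999996	1	100	100	100	100	100	100	100	100	100
contam_gfp	50	500	5	50	500	5	50	500	5	100	100	100	100	100	100	100	100	100
contam_dsred	50	5	500	50	5	500	50	5	500	100	100	100	100	100	100	100	100	100
notch_inh_1	100	10	10	100	10	10	100	10	10	100	100	400	100	100	25	100	400	100
notch_act_1	100	10	10	100	10	10	100	10	10	100	100	25	100	100	400	100	25	100
boundary_act	100	10	10	100	10	10	100	10	10	100	100	200	100	100	300	100	100	100
boundary_inh	100	10	10	100	10	10	100	10	10	100	100	1	1	1	0.66700000000000004	1	1	1
boundary_dbz_up	100	10	10	100	10	10	100	10	10	100	100	1	1	1	2.5	1	2	1
boundary_dbz	100	10	10	100	10	10	100	10	10	100	100	2	1	1	0.5	1	0.625	1
dbz_removed_act	100	10	10	100	10	10	100	10	10	100	100	1	1	1	4	1	3.3999999999999999	1
dbz_removed_inh	100	10	10	100	10	10	100	10	10	100	100	2	1	1	0.5	1	0.59999999999999998	1
edn1_inh_1	100	10	10	100	10	10	100	10	10	400	100	100	100	25	100	100	100	100
edn1_act_1	100	10	10	100	10	10	100	10	10	25	100	100	100	400	100	100	100	100
co_pos_1	100	10	10	100	10	10	100	10	10	25	100	25	100	400	400	100	25	100
co_neg_1	100	10	10	100	10	10	100	10	10	400	100	400	100	25	25	100	400	100
antag_induced	10	1	1	120	1	1	120	1	1	25	100	400	100	400	25	100	400	100
zero_at_20	0	10	10	50	10	10	60	10	10	100	100	100	100	100	100	100	100	100
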