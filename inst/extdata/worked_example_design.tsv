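sample_id	population	stage_hpf	condition
wt_dp_20	double_positive	20	wt
wt_gfp_20	gfp_only	20	wt
wt_dsred_20	dsred_only	20	wt
wt_dp_28	double_positive	28	wt
wt_gfp_28	gfp_only	28	wt
wt_dsred_28	dsred_only	28	wt
wt_dp_36	double_positive	36	wt
wt_gfp_36	gfp_only	36	wt
wt_dsred_36	dsred_only	36	wt
edn1_mut_36	double_positive	36	edn1_mut
edn1_ctrl_36	double_positive	36	edn1_ctrl
jag1b_mut_36	double_positive	36	jag1b_mut
jag1b_ctrl_36	double_positive	36	jag1b_ctrl
edn1_oe_36	double_positive	36	edn1_oe
nicd_oe_36	double_positive	36	nicd_oe
hs_ctrl_36	double_positive	36	hs_ctrl
dbz_36	double_positive	36	dbz
vehicle_ctrl_36	double_positive	36	vehicle_ctrl
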