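sample_id	gene	filter_status	exac_maf	impact	sift	polyphen	extra_note
S1	G1	PASS	0.001	HIGH	deleterious	benign	retained_sift
S1	G1	PASS		MODERATE			retained_no_predictions
S1	G2	PASS	0.005	HIGH	tolerated	probably_damaging	retained_polyphen
S2	G2	PASS	NA	HIGH	deleterious	probably_damaging	retained_both
S3	G3	PASS	0.002	MODERATE	deleterious (low confidence)		retained_sift_lc
S4	G2	PASS	NA	HIGH	deleterious	probably_damaging	retained_but_sample_lacks_expression
S1	G3	germline_risk	NA	HIGH	deleterious	probably_damaging	removed_non_pass
S2	G3	PASS	0.02	HIGH	deleterious	probably_damaging	removed_maf
S3	G1	PASS	NA	LOW	deleterious	probably_damaging	removed_impact
S3	G2	PASS	0.001	MODERATE	tolerated	benign	removed_negative_predictions
S2	G1	PASS	NA	MODERATE	tolerated		removed_one_sided_negative
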