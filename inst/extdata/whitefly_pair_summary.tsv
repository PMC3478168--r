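comparison	n_pairs	total_aligned_kb	longest_aligned_bp	mean_homology_pct	min_homology_pct	max_homology_pct	sd_reported
MEAM1_AsiaII3	2966	1434.4	3081	98.27	70.43	100	0.00024
MED_AsiaII3	2529	1072.1	2919	98.16	79.68	100	0.00029
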