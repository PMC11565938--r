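name	kind	default	warmup_step
uniquely_mapped_only	binary	0	1
use_second_alignment	binary	0	1
max_dp_table_size	integer	10000	2000
max_edit_distance	integer	10	2
max_num_exons	integer	1000	200
min_bundle_gap	integer	50	10
min_exon_length	integer	20	4
min_flank_length	integer	3	1
min_mapping_quality	integer	1	1
min_num_hits_in_bundle	integer	20	4
min_router_count	integer	1	1
min_splice_boundary_hits	integer	1	1
min_subregion_gap	integer	3	1
min_subregion_length	integer	15	3
min_transcript_length_base	integer	150	30
min_transcript_length_increase	integer	50	10
max_intron_contamination_coverage	float	2	0.4
min_subregion_overlap	float	1.5	0.3
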