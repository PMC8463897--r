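species	key	value
O_nova	regions_phased	281
O_nova	region_median_length_bp	358
O_nova	regions_testable	223
O_nova	regions_delta_negative	115
O_nova	regions_asex_significant	69
O_nova	regions_au_untestable	14
O_nova	phaseable_sites	163418
O_nova	sites_asex_significant	37693
O_subpectinata	regions_phased	275
O_subpectinata	region_median_length_bp	563
O_subpectinata	regions_testable	268
O_subpectinata	regions_delta_negative	6
O_subpectinata	regions_au_untestable	5
O_subpectinata	phaseable_sites	355249
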