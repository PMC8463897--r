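species	population	individual	lineage	fis	n_sites
O_nova	H	H1	I	-0.390	5414
O_nova	H	H2	I	-0.361	5414
O_nova	H	H3	II	-0.243	3471
O_nova	KF	KF1	II	-0.246	3471
O_nova	KF	KF2	II	-0.296	3471
O_nova	KF	KF3	NA	NA	NA
O_nova	SA	SA1	I	-0.361	5414
O_nova	SA	SA2	NA	NA	NA
O_nova	SA	SA3	I	-0.398	5414
O_subpectinata	H	H1	NA	0.015	12730
O_subpectinata	H	H2	NA	-0.034	12730
O_subpectinata	H	H3	NA	0.001	12730
O_subpectinata	KF	KF1	NA	-0.006	40145
O_subpectinata	KF	KF2	NA	0.023	40145
O_subpectinata	KF	KF3	NA	0.002	40145
O_subpectinata	SA	SA1	NA	-0.018	10197
O_subpectinata	SA	SA2	NA	0.058	10197
O_subpectinata	SA	SA3	NA	-0.019	10197
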