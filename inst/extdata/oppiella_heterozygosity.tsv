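species	population	individual	pct_het
O_nova	H	H1	1.273
O_nova	H	H2	1.285
O_nova	H	H3	0.741
O_nova	KF	KF1	0.746
O_nova	KF	KF2	0.771
O_nova	KF	KF3	0.414
O_nova	SA	SA1	1.268
O_nova	SA	SA2	0.441
O_nova	SA	SA3	1.288
O_subpectinata	H	H1	0.619
O_subpectinata	H	H2	0.665
O_subpectinata	H	H3	0.640
O_subpectinata	KF	KF1	0.599
O_subpectinata	KF	KF2	0.581
O_subpectinata	KF	KF3	0.591
O_subpectinata	SA	SA1	0.723
O_subpectinata	SA	SA2	0.685
O_subpectinata	SA	SA3	0.743
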