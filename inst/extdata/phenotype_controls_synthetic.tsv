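trait	control_mean	control_sd	unit
developmental_time_days	19.5	1.0	days
weight	150	18	mg
length	13.0	0.8	mm
ovarioles	60	12	count
eggs	90	20	count
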