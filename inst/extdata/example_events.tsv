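# illustrative synthetic example in the event-table schema (not empirical data)
species	event	pc_day	is_primate	event_class
mouse	retinal_ganglion_cell_peak	13.5	0	other
mouse	cortical_layer6_peak	14.2	0	cortical
mouse	hippocampus_ca1_peak	15.1	0	limbic
mouse	eye_opening	29.5	0	other
rat	retinal_ganglion_cell_peak	15.8	0	other
rat	cortical_layer6_peak	16.9	0	cortical
rat	hippocampus_ca1_peak	17.7	0	limbic
rat	eye_opening	36.3	0	other
ferret	cortical_layer6_peak	27.0	0	cortical
ferret	hippocampus_ca1_peak	29.4	0	limbic
ferret	eye_opening	73.2	0	other
macaque	retinal_ganglion_cell_peak	48.6	1	other
macaque	cortical_layer6_peak	54.5	1	cortical
macaque	hippocampus_ca1_peak	59.0	1	limbic
macaque	eye_opening	168.0	1	other
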