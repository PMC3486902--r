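d6a49c5ecf38883c5fe4ef53fb8babce  table1_patients.tsv
076987b5d622568e52282e2ca3fb0e3b  table2_carrier_cases.tsv
adb8800efa9905bcd087a5b1803e7f98  table3_control_groups.tsv
8879253c4e137a39ead6a1d190eb6cb1  table5_weighted_controls.tsv
a28dbf1cbfebd86ea3f73fa13a7606c2  embryo_level_robertsonian.tsv
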