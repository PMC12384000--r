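key	value
isoform	2N4R
isoform_length	441
total_potential_sites	85
potential_Ser	45
potential_Thr	35
potential_Tyr	5
transcribed_rows_CaMKII	6
transcribed_rows_Cdk5	10
transcribed_rows_GSK3beta	4
transcribed_rows_MARK4	1
transcribed_rows_CN	5
transcribed_rows_unassigned	2
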