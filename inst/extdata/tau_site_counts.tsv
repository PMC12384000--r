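enzyme	n_sites	residue_classes	citation
GSK3beta	43	S/T	kinase-site-counts
Cdk5	13	S/T	kinase-site-counts
p38MAPK	19	S/T	kinase-site-counts
DYRK1A	3	S/T	kinase-site-counts
MARK4	2	S/T	kinase-site-counts
Src	1	Y	kinase-site-counts
Fyn	1	Y	kinase-site-counts
c-Abl	1	Y	kinase-site-counts
ROCK	3	Y	kinase-site-counts
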