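name	packaged	printed_start	printed_classes	printed_count	status	note
Tau-R2	TRUE	286	1-14	1	clean	printed start label 286 for an 18-residue string spanning 19 labelled positions; canonical 2N4R placement 287-304 reconciles Ser289/Ser293 with the serines in the string; both offsets carried
CaMKIIA	TRUE	296	1-5-10	1	clean	single curated 1-5-10 motif, anchors Leu299/Ile303/Leu308 (fingerprint LIL)
GSK3beta-CaMBD1	TRUE	81	1-12,1-5-10	2	curation-ambiguous	exhaustive curated scan (core anchors) finds additional motifs (a 1-8-13, a second 1-12 and a 1-14) beyond the two reported
GSK3beta-CaMBD2	TRUE	134	1-12,1-12,1-14	4	curation-ambiguous	reported count four but only three classes listed; exhaustive curated scan finds 2
GSK3beta-CaMBD3	TRUE	193	1-10,1-10,1-12	3	curation-ambiguous	exhaustive curated scan finds 4 (one 1-10, one 1-12, one 1-14, one 1-8-14)
Cdk5-CaMBD1	TRUE	17	1-12,1-12,1-14	2	label-inconsistent	reported count two but three classes listed; 25 printed letters for an 18-residue span (likely duplication typo); excluded from count-based tests
Cdk5-CaMBD2	TRUE	133	1-10,1-10,1-16,1-14	4	curation-ambiguous	reported 1-16 not reproducible with core anchors; exhaustive curated scan finds 6
ROCK1-CaMBD1	TRUE	86	1-12,1-10	2	clean	printed end label 105; end recomputed as 104 from string length (start label authoritative)
ROCK1-CaMBD2	TRUE	1133	1-12,1-8-13	2	curation-ambiguous	exhaustive curated scan finds 3 (the raw 1-14 is subsumed by an additional 1-8-14 the report does not list)
CN-CaMBD	TRUE	391	1-16,1-8-14,1-14,1-12,1-10	5	curation-ambiguous	reported 1-12 requires a Met anchor (extended set); curated core scan finds five motifs but with a different class multiset (two 1-10, no 1-12)
TGM2-CaMBD1	TRUE	414	1-16,1-12,1-5-10	3	clean	curated scan reproduces the three reported motifs; the raw 1-10 is subsumed by the coterminal 1-5-10
TGM2-CaMBD2	TRUE	665	1-12,1-12,1-8-14,1-10,1-10	5	curation-ambiguous	exhaustive curated scan finds 6 (three 1-12, one 1-10, one 1-16, one 1-8-14)
MARK4-CaMBD	FALSE	NA	1-14,1-12	2	curation-ambiguous	sequence shown only as a figure image and not packaged; reported class 1-1-12 recorded as a typo for 1-12
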