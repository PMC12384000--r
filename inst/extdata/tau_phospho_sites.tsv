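position	residue	enzyme	direction	effect_pct	stage	citation	note
131	S	CaMKII	phosphorylates	NA	NA	camkii-kinase
135	T	CaMKII	phosphorylates	NA	NA	camkii-kinase
212	T	CaMKII	phosphorylates	NA	NA	camkii-kinase	listed twice in the source site list; stored once
214	S	CaMKII	phosphorylates	NA	NA	camkii-kinase	listed twice in the source site list; stored once
262	S	CaMKII	phosphorylates	NA	pre	camkii-kinase;prephos-network	early aggregation-initiating site
356	S	CaMKII	phosphorylates	NA	pre	camkii-kinase;prephos-network	early aggregation-initiating site
181	T	Cdk5	phosphorylates	NA	NA	cdk5-kinase
202	S	Cdk5	phosphorylates	NA	NA	cdk5-kinase	hyperphosphorylated in post-mortem AD brain
205	T	Cdk5	phosphorylates	NA	NA	cdk5-kinase	hyperphosphorylated in post-mortem AD brain
212	T	Cdk5	phosphorylates	NA	NA	cdk5-kinase
217	T	Cdk5	phosphorylates	NA	NA	cdk5-kinase
235	S	Cdk5	phosphorylates	NA	NA	cdk5-kinase
262	S	Cdk5	phosphorylates	NA	pre	prephos-network	prephosphorylation opening later hyperphosphorylation
356	S	Cdk5	phosphorylates	NA	pre	prephos-network	prephosphorylation opening later hyperphosphorylation
369	S	Cdk5	phosphorylates	NA	NA	cdk5-kinase	possible typo for Ser396 in the source; transcribed as printed
404	S	Cdk5	phosphorylates	NA	NA	cdk5-kinase
231	T	GSK3beta	phosphorylates	NA	hyper	prephos-network	disease-linked hyperphosphorylation site
235	S	GSK3beta	phosphorylates	NA	hyper	prephos-network	disease-linked hyperphosphorylation site
396	S	GSK3beta	phosphorylates	NA	hyper	prephos-network	disease-linked hyperphosphorylation site
404	S	GSK3beta	phosphorylates	NA	hyper	prephos-network	disease-linked hyperphosphorylation site
262	S	MARK4	phosphorylates	NA	hyper	mark4-kinase	hyperphosphorylated by MARK4 in AD brain
199	S	CN	dephosphorylates	38	dephos	cn-phosphatase
217	T	CN	dephosphorylates	32	dephos	cn-phosphatase
262	S	CN	dephosphorylates	63	dephos	cn-phosphatase	R1 domain
396	S	CN	dephosphorylates	78	dephos	cn-phosphatase	R4 domain
422	S	CN	dephosphorylates	32	dephos	cn-phosphatase
289	S	unassigned	phosphorylates	NA	NA	tau-r2-cambd	phosphorylated in AD; kinase not specified
293	S	unassigned	phosphorylates	NA	NA	tau-r2-cambd	phosphorylated in AD; kinase not specified
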