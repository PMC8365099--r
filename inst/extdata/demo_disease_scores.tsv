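# Demonstration pathogenicity-score lookup. Disease scores and tRNA
# classes are external inputs to the pipeline (e.g. MToolBox disease
# scores, MitoTIP classes); this table only covers variants used in the
# package examples and tests. The m.7824C>T disease score is the
# published value; the remaining scores are illustrative placeholders
# consistent with the variants' reported pathogenicity status.
position	ref	alt	disease_score	trna_class
7824	C	T	0.835	NA
3460	G	A	0.62	NA
11778	G	A	0.71	NA
9185	T	C	0.78	NA
8993	T	C	0.82	NA
10377	C	T	0.21	NA
3243	A	G	NA	likely_pathogenic
5540	G	A	NA	possibly_pathogenic
4336	T	C	NA	possibly_benign
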