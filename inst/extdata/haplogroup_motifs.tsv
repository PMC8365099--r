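# Demonstration haplogroup motif table (simplified subsets of
# PhyloTree-style defining variants, rCRS-relative). Motifs are
# an input to the pipeline; supply your own table for real data.
haplogroup	position	ref	alt
H	263	A	G
H	750	A	G
H	1438	A	G
H	4769	A	G
H	8860	A	G
H	15326	A	G
H1	263	A	G
H1	750	A	G
H1	1438	A	G
H1	4769	A	G
H1	8860	A	G
H1	15326	A	G
H1	3010	G	A
J1c2	73	A	G
J1c2	263	A	G
J1c2	750	A	G
J1c2	1438	A	G
J1c2	4769	A	G
J1c2	8860	A	G
J1c2	15326	A	G
J1c2	295	C	T
J1c2	462	C	T
J1c2	489	T	C
J1c2	2706	A	G
J1c2	3010	G	A
J1c2	4216	T	C
J1c2	7028	C	T
J1c2	10398	A	G
J1c2	11251	A	G
J1c2	11719	G	A
J1c2	12612	A	G
J1c2	13708	G	A
J1c2	14766	C	T
J1c2	14798	T	C
J1c2	15452	C	A
J1c2	16069	C	T
J1c2	16126	T	C
U5a1	73	A	G
U5a1	263	A	G
U5a1	750	A	G
U5a1	1438	A	G
U5a1	4769	A	G
U5a1	8860	A	G
U5a1	15326	A	G
U5a1	2706	A	G
U5a1	3197	T	C
U5a1	7028	C	T
U5a1	9477	G	A
U5a1	11467	A	G
U5a1	11719	G	A
U5a1	12308	A	G
U5a1	12372	G	A
U5a1	13617	T	C
U5a1	14766	C	T
U5a1	16192	C	T
U5a1	16256	C	T
U5a1	16270	C	T
D1g	73	A	G
D1g	263	A	G
D1g	750	A	G
D1g	1438	A	G
D1g	4769	A	G
D1g	8860	A	G
D1g	15326	A	G
D1g	489	T	C
D1g	2706	A	G
D1g	4883	C	T
D1g	5178	C	A
D1g	7028	C	T
D1g	8701	A	G
D1g	9540	T	C
D1g	10398	A	G
D1g	10400	C	T
D1g	11719	G	A
D1g	12705	C	T
D1g	14766	C	T
D1g	14783	T	C
D1g	15043	G	A
D1g	16223	C	T
D1g	16362	T	C
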