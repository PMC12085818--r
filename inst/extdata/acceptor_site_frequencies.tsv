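# Approximate human U2 acceptor-site base frequencies (percent) for the
# 23-mer window (20 intronic + 3 exonic bases): polypyrimidine tract,
# invariant AG, and the first exonic bases.  Consensus-derived
# approximation bundled with the package, not a copy of any published
# table.
pos	A	C	G	T
-20	11	29	13	47
-19	10	31	12	47
-18	10	30	11	49
-17	9	31	12	48
-16	9	32	11	48
-15	9	31	11	49
-14	8	32	11	49
-13	8	33	10	49
-12	8	33	10	49
-11	8	34	10	48
-10	8	34	9	49
-9	8	35	9	48
-8	8	35	9	48
-7	8	36	8	48
-6	8	36	8	48
-5	7	37	7	49
-4	24	30	21	25
-3	3	65	2	30
-2	100	0	0	0
-1	0	0	100	0
1	25	13	52	10
2	24	30	22	24
3	21	27	27	25
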