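# Approximate human U2 donor-site base frequencies (percent) for the 9-mer
# window (3 exonic + 6 intronic bases), consensus CAG|GTRAGT.  Consensus-
# derived approximation bundled with the package, not a copy of any
# published table.
pos	A	C	G	T
-3	33	37	18	12
-2	61	13	12	14
-1	10	3	80	7
1	0	0	100	0
2	0	0	0	100
3	60	3	34	3
4	68	9	12	11
5	9	5	84	2
6	17	17	19	47
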