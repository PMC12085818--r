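# Synthetic exonic-splicing-enhancer position weight matrices in the style
# of the classic SR-protein motif sets (SRSF1, SRSF1-IgM, SRSF2/SC35,
# SRSF5).  These are consensus-derived stand-ins constructed for this
# package, NOT the published ESEfinder matrices; users may supply their
# own matrix files in the same dialect.  Weights are log2 odds; a window
# is a hit when its summed score reaches the motif threshold.
motif	threshold	pos	A	C	G	T
SRSF1	2.0	1	0.2	1.2	0.4	-1.0
SRSF1	2.0	2	1.2	-1.0	0.4	-1.0
SRSF1	2.0	3	-1.0	1.2	0.4	0.2
SRSF1	2.0	4	1.2	0.2	0.4	-1.0
SRSF1	2.0	5	-1.0	1.2	0.4	0.2
SRSF1	2.0	6	0.2	-1.0	1.2	0.4
SRSF1	2.0	7	1.2	0.4	0.2	-1.0
SRSF1igM	1.9	1	0.4	-1.0	1.2	0.2
SRSF1igM	1.9	2	1.2	-1.0	0.4	-1.0
SRSF1igM	1.9	3	1.2	0.2	0.4	-1.0
SRSF1igM	1.9	4	0.2	-1.0	1.2	0.4
SRSF1igM	1.9	5	1.2	-1.0	0.4	0.2
SRSF1igM	1.9	6	1.2	0.2	0.4	-1.0
SRSF1igM	1.9	7	0.4	-1.0	1.2	0.2
SRSF2	2.4	1	-1.0	0.2	1.2	0.4
SRSF2	2.4	2	-1.0	0.4	1.2	0.2
SRSF2	2.4	3	0.2	1.2	0.4	-1.0
SRSF2	2.4	4	-1.0	1.2	0.2	0.4
SRSF2	2.4	5	-1.0	0.4	0.2	1.2
SRSF2	2.4	6	0.2	1.2	-1.0	0.4
SRSF2	2.4	7	-1.0	0.4	0.2	1.2
SRSF2	2.4	8	0.2	0.4	1.2	-1.0
SRSF5	2.7	1	0.4	0.2	-1.0	1.2
SRSF5	2.7	2	-1.0	1.2	0.4	0.2
SRSF5	2.7	3	1.2	0.2	0.4	-1.0
SRSF5	2.7	4	0.2	-1.0	1.2	0.4
SRSF5	2.7	5	-1.0	1.2	0.4	0.2
SRSF5	2.7	6	1.2	0.2	0.4	-1.0
SRSF5	2.7	7	0.2	0.4	1.2	-1.0
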