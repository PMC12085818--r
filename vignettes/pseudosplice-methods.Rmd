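---
title: "Models and design decisions in pseudosplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in pseudosplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudosplice)
```

# Scope

`pseudosplice` characterises deep-intronic single-nucleotide variants that
activate pseudoexons (PEs) — intronic segments spliced into mRNA through
cryptic acceptor/donor sites — and designs antisense molecules (modified
U7 snRNA and circular-RNA carriers) that block them.  The package covers
the computational side of a minigene-based characterisation workflow:
candidate-variant filtering from SpliceAI delta scores, splice-site
strength scoring, background-splicing analysis of splice-junction
compendium tables, PE naming and coding-consequence annotation,
fragment-analysis isoform quantification, antisense candidate ranking, and
a stochastic minigene-splicing simulator that stands in for the wet-lab
assay so that every stage is testable without external data.

# Coordinate conventions

All internal coordinates are 0-based half-open on the **gene sense
strand** of the supplied locus sequence.  Genes annotated on the genomic
minus strand are converted once at the I/O boundary with
`flipToSenseStrand()` (reverse complement plus interval flip).  One
unambiguous frame keeps all splice-site arithmetic — window extraction,
PE lengths, HGVS offsets — free of strand special cases.

HGVS-like `c.` parsing supports exactly the intronic-offset SNV subset
the workflow needs (`c.N+M`, `c.N-M`, optional `ref>alt` tail); anything
else is rejected loudly rather than half-interpreted.

# Splice-site models

## Position weight matrices

The built-in scorer is a log2-odds position weight matrix over the
standard maximum-entropy window conventions: donors are scored on a 9-mer
(3 exonic + 6 intronic bases), acceptors on a 23-mer (20 intronic + 3
exonic).  The matrices are built at load time from packaged
percent-frequency tables (approximate human consensus frequencies
authored for this package) with pseudocount 0.25 against a uniform
background.  On this scale the packaged donor matrix tops out at ~12.8
and the acceptor at ~22.1; 0 means "indistinguishable from background".

A window only counts as a *site* when it also carries the obligate core
dinucleotide — GT for donors, AG for acceptors.  Additive matrices
otherwise report pyrimidine-rich windows with no AG at all as
"acceptors", which is biologically meaningless and, in the simulator,
floods the ensemble with phantom isoforms.  The core rule is applied
consistently in latent-site scanning and in the per-variant delta report.

## Maximum-entropy scoring

`scoreSiteMaxent()` scores sites in the published maximum-entropy model's
units, but the published parameter tables are not redistributed: the user
supplies a directory of TSV component tables (`readMaxentModel()`), where
each component maps a sub-window k-mer to a probability and contributes
`± log2(w)` as numerator or denominator.  A full-k-mer toy model is a
single numerator component; converted published tables factorise the
23-mer acceptor into overlapping components.  Without tables the
operation is unavailable (a clear error at call time, nothing at load
time).  The tests exercise the contract exhaustively on toy models; the
published reference values for the intron-4 PE acceptors (−5.33 and
−1.44) can be reproduced only with the published tables and the genomic
sequence, which the user must supply.

## Variant delta reports

`variantSiteDelta()` scores every donor/acceptor window overlapping the
variant in the reference and alternate sequence.  Reporting uses two
config keys: a floor (default 0 — the background-odds point) and a gain
delta (default 1 model unit).  Classification reflects the largest gain:
a window reportable only on the alternate allele is a creation
(`donor_gain`/`acceptor_gain`); a gain on an already-reportable window is
a `strengthening`.  The literature gives no numeric site-strength cutoff
for these calls, which is why both knobs are configuration, not
constants.

## ESE motifs

Antisense design treats SC35 (SRSF2) motif clusters as preferred targets.
The packaged motif set (SRSF1, SRSF1-IgM, SRSF2, SRSF5) consists of
**synthetic consensus-derived stand-ins** in the style of the classic
ESEfinder matrices — the published matrices are not redistributable — and
is clearly labelled as such in `ese_matrices_synthetic.tsv`; users with
access to the published set can drop it in using the same file dialect.
Because the default thresholds are also synthetic, ESE hit counts from
the bundled set should be read comparatively (within one analysis), not
as calibrated occupancy predictions.

# Variant selection cascade

`selectVariants()` implements a four-rule cascade: (1) single-nucleotide
variants only; (2) at least 100 bp (the optimal minimal-intron length,
configurable) from every annotated exon; (3) tiering by the larger of the
acceptor-gain and donor-gain delta scores — high at ≥ 0.5, medium in
(0.2, 0.5) *provided* the variant lies within 5 000 bp of a high-tier
anchor (the distance at which neighbouring exons are cloned into the same
minigene, hence "same minigene"); (4) exclusion of common variants
(MAF > 1%) unless explicitly allow-listed.  The allow-list is
deliberately manual: a common variant should only survive on outside
evidence (the motivating case is a variant hidden behind an apparent
polymorphism by a protective variant in cis), never automatically.

Every rule is evaluated for every variant, so outcomes are independent of
rule order and each exclusion carries the complete set of violated rules;
variants with no prediction are reported as excluded with reason
`no_prediction`, never dropped.

# Background splicing and PE annotation

`callBackgroundEvents()` takes a Snaptron-style junction table (4 named
columns; start, end, read count, sample count).  A junction is
*discordant* when its coordinate pair matches no annotated intron — an
operational definition; the compendium's internal notion is not
reproduced.  Discordant junctions anchored at both flanks of one intron
and bracketing a segment of at most `max_pe_length` (default 500 bp,
comfortably above the longest PE the workflow targets, 376 bp) pair into
`pe_inclusion` events; junctions connecting a donor boundary to a later
acceptor boundary are `exon_skip`; everything else is reported as
`cryptic_site` evidence rather than silently dropped.  The length cap
exists because junctions cannot be phased across molecules: without it,
every left anchor would combine with every right anchor in a
PE-dense intron into implausibly long chimeric "exons".  A PE event's
support is the smaller of its two junction counts (a conservative
molecule estimate).

Naming follows the longest-isoform scheme: overlapping isoforms form a
group (wild-type and variant-activated isoforms are grouped separately —
the wild-type status is an input flag, not inferred), the longest takes
the base name (`PE-k`, or `PE-wt-k` for wild-type groups, numbered 5′→3′),
and shorter isoforms get `_D2…` (alternative donors, shared acceptor) or
`_A2…` (alternative acceptors, shared donor) by decreasing length.
Numbering is scoped to one call: names are stable within an analysis
context, and the package does not try to reproduce any externally
assigned global numbering.

PTC annotation splices the PE into the mRNA in silico and scans the
PE-containing reading frame for a stop codon upstream of the annotated
terminator; frameshift status is pure length arithmetic (`length %% 3`).
Non-coding models disable PTC annotation (undetermined), and PEs lacking
one splice site (alternative first/terminal exons) are outside the
caller's model — their junctions surface as `cryptic_site` evidence.

# Isoform quantification

Fragment-analysis peaks are matched to expected amplicon lengths by
nearest neighbour within a sizing tolerance (default 2 bp, typical
capillary precision); expected lengths closer than twice the tolerance
are a configuration error because the assignment would be ambiguous.
Fractions are raw area over total area; whether published percentages are
area- or molar-normalised is not stated, so v1 reports raw area and
exposes a per-bp area bias term in the simulator rather than silently
renormalising.  The 5% display rule hides minor isoforms from printed
output only — all computations use full-precision fractions.
Fold-changes are reported to one decimal, matching the convention of the
quantities they reproduce (3.2, 12.8, 3.8); a zero test fraction is a
"complete loss" sentinel rather than an infinity.

Antisense efficacy is the reduction of all PE-containing isoforms
(percentage points and relative), carrying along the correct-transcript
fraction and the neighbour-exon-skip fraction, the latter because
blockers measurably increase skipping of the neighbouring canonical
exon.  A paired wild-type/variant quantification is called
splice-altering when the correct-transcript fraction drops by more than
10 points (configurable) — the quantitative reading of a "clear
difference" between constructs.

# Antisense design

Candidates are every window of the modality's allowed lengths
(modU7snRNA 18–30 nt, circRNA 40–150 nt by default) over the PE ± 50 bp
of flanking intron, scored on three criteria:

* **site overlap** — fraction of a splice-site core window (donor 9-mer,
  acceptor 23-mer) covered, 1 when fully covered;
* **ESE coverage** — summed scores of above-threshold SC35 hits contained
  in the window, length-normalised;
* **accessibility** — mean openness of the target under the secondary-
  structure ensemble below.

The composite score is a weighted sum (defaults 1, 1, 1) minus 0.5 × a
length penalty (relative excess over the modality optimum, 25 nt for U7
and 80 nt for circRNA — beyond which longer antisense sequences add
little).  Equal default weights are deliberate: in practice no single
criterion dominates (splice-site-targeting blockers are sometimes the
least effective), so the ranking should not hard-code a hierarchy; all
weights are configuration.  A shift-by-k generator (default ±5 bp)
produces the standard rescue variants for a candidate suspected of
self-structure or processing problems.

## The accessibility ensemble

Openness at base *i* is 1 − P(*i* paired) over the Boltzmann ensemble of
nested, pseudoknot-free structures in which every Watson–Crick or G·U
pair contributes a constant weight `exp(pair_score / temperature)`
(default e) and hairpin loops span ≥ 3 bases.  The partition function
uses the standard inside recursion on the unambiguous leftmost
decomposition, an outside pass yields per-base probabilities, and
per-base rescaling keeps doubles in range (an adaptive retry adjusts the
scale; probabilities are scale-free).  This unit-pair-score model is used
instead of full nearest-neighbour thermodynamics on purpose: ranking
needs relative openness, not free energies, and the simple ensemble
admits an exhaustive enumeration oracle — the test suite verifies the
implementation against brute-force structure enumeration for hundreds of
random sequences up to 18 nt.  An external thermodynamic folding tool can
be plugged in by wrapping its per-base pairing probabilities in an
`AccessibilityProfile` and passing it to the design functions.  Regions
are capped at 2 000 nt (O(n³) recursions); fold longer regions in
windows.

# The minigene simulator

`buildMinigene()` clones a locus fragment between two constitutive vector
exons V1/V2 and injects variants (wild-type and mutant constructs share
coordinates and differ at exactly the injected bases).  The site registry
is built by scanning the insert with the packaged matrices: windows with
the core dinucleotide scoring at or above `site_floor` (default 0).

`simulateSplicing()` enumerates candidate isoforms — the correct product,
each single-exon skip, and each registered acceptor/donor pair within one
intronic segment whose span lies in `pe_length_range` (default
40–500 bp) — and assigns weights: a PE isoform gets the product of the
logistic usabilities σ(score) of its two sites (midpoint 0, slope 0.5 in
model-score units: a background-level site is a coin flip, a +6 site is
~95% usable) times the no-skip factors; skipping uses per-exon
propensities.  Antisense blocking multiplies σ of a covered site by
(1 − ε·coverage of the site's core window).  Molecule counts are drawn
from a single multinomial, fully reproducible per seed (the RNG state is
restored afterwards).  This is the simplest generative model consistent
with competitive isoform usage — suboptimal-but-functional acceptors
yield minor isoforms; saturated sites yield dominant ones.  What it does
**not** model: kinetic/co-transcriptional splicing, NMD decay (fractions
are pre-decay), replicate-level biological variance (no replicate
variance is published for the three-replicate assays; the observables
carry one Gaussian sizing-noise term, chosen for testability), stutter or
pull-up artifacts.  Because the logistic caps usability at 1, dominant
PEs compete with, rather than abolish, the correct product; the
simulator therefore compresses the extreme outcomes (complete loss of
correct transcript) seen in cells.

`emitObservables()` produces the two assay observables: a peak table (one
peak per isoform, fragment length + N(0, 0.5 bp) sizing noise, area
proportional to count with an optional per-bp dye bias, off by default)
and a junction table in locus coordinates (junctions touching the vector
arms have no locus analogue and are omitted).  Both round-trip through
the package readers.  A cryptic vector acceptor reproducing the
intron-fragment-retention minigene artifact can be registered via
`vector_cryptic_acceptor`; it is off by default.

# The packaged demo locus

`demoLocus()` deterministically builds a 14-exon toy gene (~14.5 kb) whose
intron landscape mirrors the pseudoexon biology the pipeline addresses: a
PE-dense intron 1 with a wild-type PE carrying two alternative donors
(223/170 bp), a long intron 4 with a cluster of weak PE acceptors, a
53 bp PE in intron 8, and a polypyrimidine-tract-controlled 376 bp PE in
intron 9.  Exon boundaries are chosen so that the published variant names
(`c.121-210C>T`, `c.422+933G>T`, …) resolve to internally consistent toy
coordinates, and PE lengths follow the published values; the genomic
coordinates themselves are synthetic.  Every planted splice-site window
is derived from the packaged matrices by a deterministic greedy tuner
(with neighbour-boundary suppression so a cassette contributes exactly
its intended sites), the intronic background comes from a fixed
linear-congruential stream, and decoy windows are disrupted by a
convergent C-writing depletion pass — real introns are likewise depleted
of decoy sites, and the fixture enforces it so simulated isoform sets are
exactly the designed ones.  No R RNG state is consumed.

`demoVariantTable()` carries the fifteen candidate variants: the eight
minigene-confirmed ones with their published delta scores and population
facts (six of the eight at DS ≥ 0.5, the common variant with its 3% MAF
and allow-list status), plus seven co-located candidates whose scores are
synthetic fill-ins chosen once to satisfy the stated group structure
(two more high-score, five medium).  `demoJunctionTable()` provides a
118-row Snaptron-style table whose twenty strongest-supported events are
nine wild-type PE groups (the fourth is the 223/170 bp shared-acceptor
pair) and skipping of the four weak canonical exons.
`demoMinigenePanel()` simulates the wild-type/mutant construct pair for
any of the fifteen variants at n = 10 000 molecules; isoforms closer in
length than the sizing resolution are merged to the better-supported peak
before quantification, as co-migrating fragments would be.

Passing tests on this synthetic locus demonstrate that the pipeline's
logic — filtering, calling, naming, quantification, ranking — behaves as
specified under controlled conditions; they do not validate the
biological accuracy of the matrices or the simulator against real
transcriptomes.

# Numerical choices

* Threshold comparisons in motif scanning use a 1e-9 tolerance so that
  windows at exactly a decimal threshold do not flip with summation
  order; hit ordering breaks score ties by motif name for full
  determinism.
* The accessibility partition function rescales per base and retries
  adaptively on over/underflow; results match enumeration to < 1e-9.
* Multinomial sampling and sizing noise are seeded per call and restore
  the caller's RNG state; derived seeds stay below 2³¹.
* Problem sizes used by the tests and the acceptance script — 10 000
  molecules per construct, 15 wild-type/mutant panels, 500 enumeration
  checks at ≤ 18 nt, 80-nt scan-oracle regions — were chosen as the
  smallest sizes at which sampling noise is far below the tested margins.

# Known limitations

* The PWM scorer is a fallback, not a reimplementation of the published
  maximum-entropy models; strengths on the two scales are not comparable.
* Branch-point models, hexamer ESS/ESE ensembles, and SpliceAI inference
  are out of scope; delta scores are consumed as inputs.
* The junction caller does not model PEs lacking one splice site
  (alternative first/terminal exons); their evidence surfaces as
  unclassified segments.
* Off-target screening, carrier-cassette assembly, and chemical
  modification design are not modelled.
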