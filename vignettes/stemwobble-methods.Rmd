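---
title: "Classifying 4-bp anticodon stems and modelling extended superwobble decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying 4-bp anticodon stems and modelling extended superwobble decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemwobble)
```

## Background

The anticodon arm of a canonical tRNA carries a 5-base-pair anticodon stem
(AS) closing a 7-nucleotide anticodon loop (AL) with the anticodon at
positions 34–36.  A surprisingly common deviation in bacteria is the loss
of one terminal AS pair — "unpinning" — either at the top of the stem
(distal from the loop; the AL stays 7 nt) or at the bottom (the AL grows
to 9 nt).  A tRNA-Trp with CCA anticodon, a 4-bp AS unpinned at the top,
and neither the A9C nor the Hirsh G24A substitution — the
*Blastocrithidia*-like configuration — can read the near-cognate UGA stop
codon, and in several bacterial lineages accompanies a genome-wide
stop-to-tryptophan UGA reassignment.  The generalisation examined here,
the extended superwobble rule, is that any 4-bp-AS tRNA with C at the
wobble position 34 gains C:A pairing at the third codon position and so
reads both G- and A-ending codons.

`stemwobble` implements the full analytical chain around that idea:
structural classification of tRNA gene predictions, genome-level
inventories and stop-codon statistics, the hypothesis tests used on them,
a validation procedure for putative UGA reassignments, a decoding-rule
engine, and seeded generators that produce every input with planted
ground truth.

## Structural classification

Records come from the tRNAscan-SE secondary-structure dialect
(`parse_ss_records()`), in which pairing is a string of `>`, `<` and `.`.
`pair_map()` converts it to nested index pairs by stack matching, and
`annotate_arms()` segments the pairs into helices: maximal runs of stacked
pairs, tolerating at most one single-nucleotide bulge per strand per
helix.  A second bulge on the same strand, or a simultaneous gap on both
strands (a 1×1 internal loop), splits the helix; this keeps arm
assignment unambiguous while accepting the common single-bulge stems.
The anticodon stem is the helix whose innermost pair most tightly
encloses the anticodon triplet; the acceptor is the outermost helix; the
D and T stems are the first and last remaining helices around it.

Stem length is binned by the **bulge-inclusive span**: per strand, the
number of nucleotides between and including the outermost paired
nucleotides, the larger strand deciding the bin.  A stem of four pairs
with one unpaired nucleotide in between therefore bins as 5 bp.  When the
two strand spans differ, using the maximum reproduces the bulged-strand
count regardless of which strand carries the bulge.  Bins are: `AS5`;
`AS4_top` (span 4, AL 7 nt); `AS4_bottom` (span 4, AL 9 nt); `AS4_other`
(span 4, any other AL — never Blastocrithidia-like); `OTHER`.

Canonical positions are mapped structurally, not by alignment to a
consensus: position 9 is the second nucleotide after the acceptor strand
(undefined when the linker is a single nucleotide — flags then stay
unknown and `blasto_like` is false by caution), position 24 is the
partner of the second D-stem nucleotide, and positions 27/43 are the
outermost AS pair (5-bp stems) or the unpaired nucleotides flanking the
outermost remaining pair (`AS4_top`).  The A9C/G24A flags are plain
identity checks at those mapped positions, mirroring the
pattern-matching approach such surveys use on predictor output.

Record filtering precedes classification: pseudogenes, undetermined
types (including anticodons with non-ACGU characters), and records whose
anticodon triplet does not fall fully within sequence positions 33–37
are excluded, each with an enumerated reason code.  Two conventions are
decisions rather than derivations, and users should know them: the
33–37 window is applied to raw sequence coordinates (triplet start in
33–35), not to consensus numbering; and bulged stems are binned by the
larger strand span.

## Genome inventories and statistics

A tRNA "species" is an (isotype, anticodon) pair; initiator and
elongator methionine tRNAs are distinct when the input labels them so.
Species under 0.1% of all identified tRNAs are "low abundance".
Stop-codon usage counts the terminal codon of each coding sequence —
never a genome-wide triplet scan — and under a `trp_uga` code UGA is not
a stop, so a UGA-terminated CDS is reported and excluded from the
denominator.  Correlations (4-bp fraction vs genome size; deviant-stem
fraction vs species abundance) are Pearson coefficients with the
t-transform two-sided p.

The testing toolkit mirrors the conventions of the survey it supports:
a pooled two-sample proportion Z-test (two-sided); a normality-gated
comparison that runs Shapiro–Wilk on both groups at α = 0.05 and then
either a Mann–Whitney U (normal approximation, continuity and tie
corrections) or a pooled-variance Student t — "independent t-test" is
deliberately the pooled-variance form, since Welch's test is named
separately where it is used; Welch t with Welch–Satterthwaite df;
one-way ANOVA; Cohen's d with pooled SD.

## Sequence conservation comparisons

Cohort identity comparisons (4- vs 5-bp-stem tRNA-Trp(CCA) genes in
genomes carrying both) use a built-in Needleman–Wunsch global aligner
(+1 match, −1 mismatch, −2 per gap column; linear gaps).  Percent
identity counts matches over the full alignment length, gapped and
terminal-gap columns included in the denominator.  These conventions are
declared, not claimed identical to any external aligner's, so the
supported outputs are cohort *comparisons*, not absolute identities.
At score ties the traceback takes gap moves before the diagonal, which
consolidates length differences as terminal gaps — the behaviour the
C-terminal extension measurement relies on.

## Reassignment validation

A genuine stop-to-tryptophan UGA reassignment predicts: no UGA at CDS
ends; no artificial C-terminal extensions when proteins predicted under
the reassigned code are aligned with standard-code orthologues (reading
through a genuine UGA stop would extend translation to the next
UAA/UAG); and either a suppressor tRNA with UCA anticodon or strong
upstream codon-inference support (≥ 100 consensus columns by default).
Orthogroup alignments use a center-star multiple alignment (center = the
sequence maximising summed pairwise scores, merged with "once a gap,
always a gap"), adequate for the conserved, sparsely gapped families the
procedure consumes.  Families must pass the conserved-C-terminus filter
(no gaps in the last 5 columns of the standard-code alignment) before an
extension is measured.  The reference end column is the **maximum** over
reference rows — the most conservative choice against false extension
calls; `min`/`median` are available.  Truncations are reported but never
counted as extensions.  Release-factor-2 presence is consumed as an
input flag (computing it would require external sequence databases).
The verdict is `supported` only when ends are clean, no extensions are
found and support exists; any UGA end usage or extension yields
`contradicted`; otherwise `inconclusive`.

## The decoding-rule engine

Anticodons are written 5'→3' (bases 34, 35, 36) and pair antiparallel
with the codon (34↔codon 3, 35↔codon 2, 36↔codon 1).  Four rule sets
are modelled: `strict` (Watson–Crick only), `wobble` (G34 reads U/C,
U34 reads A/G, I34 reads U/C/A), `superwobble` (an unmodified U34 reads
all four third bases), and `extended` (additionally C34 on an `AS4_top`
tRNA reads G and A via C:A pairing).  Per-tRNA readable sets are
strictly nested across models, which the tests verify as a coverage
monotonicity property.

`minimal_anticodon_set()` finds the exact minimum number of (anticodon,
stem-class) units covering all sense codons, subject to the constraint
that no chosen unit reads a codon assigned to a different amino acid or
a stop (misreading is treated as deleterious; the constraint can be
relaxed).  Because wobble only moves the third position, the problem
decomposes into independent exhaustive set covers per codon box.  In
the solver, superwobbling is a *capability*: both the unmodified
(superwobbling) and modification-restricted readings of U34 are
available units, which keeps split codon boxes feasible and makes the
minimum non-increasing from strict through extended.  Under these
declared rules the wobble minimum computes to 31 with inosine allowed,
close to but not asserted equal to the classic count of 32, whose
exact side conditions (inosine availability, stop avoidance) are not
recoverable; the solver reports its value under its stated rules.
Inosine is accepted at position 34 only; A-to-I editing itself is not
modelled.

## Synthetic data: what it emulates and what it does not

Every generator is a pure function of its integer seed.

`make_trna()` plants a cloverleaf with a 7-bp acceptor stem, 4-bp D
stem, 5-bp T stem and an anticodon stem of 2–7 pairs, with the D loop
absorbing geometry changes so the anticodon always starts at position
34.  Unpinning is encoded as a genuine mispair — both nucleotides stay
in the sequence and render as dots, exactly how a structure predictor
displays a lost pair — with defaults mimicking a C27A substitution on a
former C:G pair.  Bulges insert one unpaired nucleotide next to the
outermost pair of the chosen strand.  The generator returns the
expected classification computed from its own geometry, which the
recovery tests compare against `classify()` over the whole option
lattice.

`make_genome()` draws tRNA classes from a mixture (with an optional
explicit plan for controlled species), and emits in-frame coding
sequences of 50–150 codons whose terminal stop is UGA with the planted
probability, the remainder split between UAA and UAG.  Under `trp_uga`
all ends are UAA/UAG and internal UGA (tryptophan) codons appear at a
controlled rate.  `make_orthogroups()` evolves families from a common
ancestor by substitutions only (default 5% per site), keeps the last
five residues identical, and appends planted C-terminal extensions to
the reassigned member.  `make_replicates()` draws normal replicates
around group means for the ANOVA/Welch demonstrations.

None of this emulates real molecular evolution: sites are independent,
codon usage is uniform outside the controlled stops, families have no
indels except the planted ones, and tRNA sequences outside the
constrained positions are random.  Passing recovery tests therefore
demonstrates the correctness of the implementations under the stated
structural and statistical conditions — not robustness to the
correlated noise, biased composition or alignment ambiguity of real
genomes.

## Numerical choices and problem sizes

Coordinates are 1-based closed intervals throughout, matching the
predictor's display convention; T is normalised to U for all
comparisons while writers preserve the input alphabet.  Degenerate
inputs fail loudly: zero-variance correlations, degenerate pooled
proportions, groups below the Shapiro–Wilk minimum of three, and
all-identical identity cohorts are errors rather than silent NAs, and
skipped strata in the pipeline tables carry a reason string.  Pipeline
outputs are plain TSVs written with fixed quoting and NA conventions,
so a rerun with identical inputs, configuration and seed is
bit-identical; the manifest hashes the analysis parameters (not the
output location).

The shipped test and acceptance workloads use problem sizes chosen to
exercise each property well past its edge cases while completing a full
run in minutes on one core: ≥1000 planted tRNAs across the structural
lattice, a few hundred brute-force oracle comparisons for the pair map
and aligner, extensions of 1–50 residues in families of four 50-residue
proteins, 5000/2000 null simulations for the type-I calibrations, 1000
tRNA sets for coverage monotonicity, and a 12-genome fixture world for
the end-to-end rerun check.

## Known limitations

* Arm annotation assumes a cloverleaf-like topology; records without a
  helix distinct from the acceptor enclosing the anticodon fall into
  `OTHER` with a note rather than being force-fitted.
* The anticodon-window filter uses raw coordinates; tRNAs with long
  D-loop insertions upstream of the anticodon can be excluded even when
  consensus numbering would retain them.
* The center-star alignment is not a general MSA: with many long
  indels or low conservation it can misplace gaps; the conserved-
  C-terminus filter is the guard against that regime.
* Modified bases beyond inosine (cmo5U, lysidine and relatives) are out
  of scope; decoding predictions for tRNAs relying on them will be
  conservative.
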