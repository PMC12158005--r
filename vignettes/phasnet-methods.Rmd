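---
title: "Methods: small RNA annotation and network inference in phasnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA annotation and network inference in phasnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasnet)
```

`phasnet` implements the complete analysis arc of a plant small-RNA study:
read preprocessing, MIR and PHAS locus annotation, trigger assignment,
target prediction, degradome validation, and two-model regulatory-network
classification. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not demonstrate.

## Preprocessing and alignment

Reads are adapter-trimmed at the first exact match of the adapter's 8-nt
prefix, and discarded when shorter than 18 nt after trimming or when they
contain an ambiguous base. There is no sliding-window quality trim: for
collapsed-tag analyses the N filter and the length floor are the two
decisions that matter, and an exact, deterministic rule keeps the pipeline
reproducible byte for byte. Identical sequences are merged into tags with
per-library counts (collapse conserves each library's read total — a tested
invariant), and tags matching a non-coding RNA blacklist as an exact
substring on either strand are removed; a single mismatch is enough to
retain a tag, a deliberately conservative contamination rule.

Alignment is end-to-end and ungapped with at most 2 substitutions,
reporting *all* placements on both strands — the behaviour of the classic
short-tag aligners, which run ungapped by default; indel-tolerant alignment
would blur the 5′-end positions on which all phasing statistics rest. The
implementation is a pigeonhole seed-and-extend (each tag is cut into three
segments; any 2-mismatch alignment contains one segment exactly; exact
segment hits come from a `Biostrings` PDict and every candidate is verified
by direct comparison), and the test suite proves it identical to a
brute-force Hamming scan. Tags with more than 20 genomic placements are
dropped before locus calling; because the published criteria state this
filter under the miRNA rules only, a configuration switch
(`multimap_phas`) controls whether PHAS scanning also applies it — the
default does, which is the conservative choice and is logged.

## MIR locus calling

Same-strand hits whose consecutive starts lie within 200 nt are clustered
into candidates. The gap is not a published value: it must exceed the
largest mature/star spacing (300 nt would be split in two otherwise —
so the value trades star capture against merging distant stacks) and is
exposed in the configuration. Within a candidate, the most abundant tag of
legal length (20–22 nt) is the mature; the star is the co-clustered tag
best pairing with it under the canonical Dicer geometry — mature position
*i* pairs star position *L*−1−*i*, leaving 2-nt 3′ overhangs. Duplex
validity is direct Watson–Crick + G:U complementarity with at most 5
unpaired mature positions (the two overhang positions count, so a perfect
duplex scores 2). A full thermodynamic fold is deliberately not computed:
the published criteria constrain spacing, length and abundance, not free
energy, and a complementarity test is dependency-free and exactly
reproducible; the pair-scoring table is the single place a thermodynamic
backend would plug in.

The locus is accepted when mature + star abundance reaches at least 75 % of
the candidate's reads. Mature and star are matched with a ±1-nt tolerance
at both ends when summing, because Dicer-offset isomiRs are ubiquitous in
real stacks and strict equality would fail the 75 % rule on otherwise
clean loci; the tolerance is configurable (`isomir_tol`).

Naming is homology-first: a mature inherits the family of its best
reference match within 2 mismatches and ±1 nt of length (ties: fewest
mismatches, then lexicographic reference id); everything else is novel and
receives `miRN<k>` in genomic order, one number per distinct sequence.
Because loci are sorted genomically before naming, the result is invariant
to input row order. The "probably" flag for weakly expressed annotations
reads the ambiguous published phrase "RP10M < 10 in certain samples" as
*below 10 in every library* — the most conservative flagging — with an
any-library mode available (`probably_mode`).

## PHAS locus detection

A read's phase coordinate is its 5′ end on the plus strand and its 5′ end
+ 2 on the minus strand, folding the 2-nt 3′ overhang that Dicer leaves so
both strands of one duplex share a register. Windows of 11 cycles
(231 nt for 21-nt, 264 nt for 24-nt phasing) slide in one-period steps;
per window and register the occupancy statistics are: `N = 2 ×` window
length eligible positions (every nucleotide on both strands a potential 5′
end), `m = 2 ×` cycles in-register among them, `n` occupied positions
(≥ 1 read of exactly the period length starting there), `k` occupied
in-register. The p-value is the exact hypergeometric upper tail
`P(X ≥ k)`; the score is `(k − 2) · ln(1 + 10 P/(1 + U))` with `P` the
abundance of in-register period-length reads and `U` everything else in
the window — the `+1` guards `U = 0`, and the `k − 2` factor silences
windows with fewer than three occupied cycles. Reads of the wrong length
never count toward `P` or occupancy: a phased stack of 20-nt reads is not
21-nt phasing.

The published criteria print only the thresholds (p < 0.001, score > 10,
length > 100 bp, phased abundance > 30 %, dominant length 21/24 nt); the
formulas above are the standard constructions of the phased-siRNA
literature. An alternative, much coarser position model is available
(`position_model = "grid"`): the population collapses to the `2 × period`
strand/residue classes with the two in-register classes as successes. The
specification sketch for this alternative model was internally inconsistent
(it would set the population equal to its success count); the register-class
definition used here is the nearest coherent coarse test, and the default
`"all"` model is the one all acceptance tests exercise.

Retained windows (both thresholds strict) sharing an absolute register are
merged when overlapping or bookended. The locus span runs from the first
to the last in-register occupied position plus one period; its reported
score is the *maximum* over member windows and its p-value the minimum.
Because the window grid is anchored at the chromosome origin, a locus
whose start is not a multiple of the period may have its best window cover
ten of eleven cycles; the mirror-symmetry test therefore checks exact span
mirroring and validity of all calls rather than score equality. Dominant
length is the abundance-weighted modal read length over the locus.

## Triggers, targets, degradome

One alignment engine scores all sRNA–RNA pairings: an exhaustive
antiparallel scan over every ungapped offset plus every single-gap variant
(one unpaired sRNA base or one bulged transcript base), parameterised by
alignment diagonals so the whole scan is vectorised. Penalties follow the
Allen convention — mismatch 1, G:U 0.5, gap 2, doubled at sRNA positions
2–13; a transcript bulge sits between two sRNA positions and takes the
weight of the following one (a choice the convention leaves open). The MFE
ratio divides the duplex energy by the sRNA's perfect-complement energy
under a simplified pair model (GC −3, AU −2, GU −1, mismatch/gap 0): since
only the ratio is thresholded, the model is scale-free, a perfect duplex
scores exactly 1, and the published cut-off (> 0.65, strict) applies
unchanged; the energy table is the hook for a nearest-neighbour backend.
The published two-tool intersection for target prediction is realised as
the *conjunction* of both printed criteria — Allen < 7 and ratio > 0.65 —
on this single engine: re-running two external predictors would contradict
a self-contained artifact while preserving neither threshold any more
faithfully.

Trigger search aligns each mature miRNA against both strands of every PHAS
locus extended by 200 nt per side — reading the published "flanking
sequences (totaling 400 bp)" as 400 bp of *added* flank in total; a
per-side mode exists (`trigger_flank_mode`). Assignments report at penalty
≤ 5 (inclusive, as printed). Cleavage is predicted opposite sRNA positions
10–11, and `in_register` checks that the cleavage coordinate sets the
locus register, applying the +2 convention when the site lies on the minus
strand.

Degradome reads map to transcripts by exact match (they are
transcript-derived fragments; a mismatch tolerance would only blur 5′
ends); multi-mapping reads spread fractional weight 1/t, and the rounded
profile is kept alongside the exact one. Site categories follow the
CleaveLand convention with the median computed over *occupied* positions
only — including zero positions would make the median collapse to 0 on any
sparse transcript and inflate category 2. A ±1-nt slop around the
predicted cleavage position absorbs the one-base jitter of real degradome
5′ ends (`degradome_slop`, settable to 0). Validation requires category
≤ 3, penalty ≤ 6 and at least one read.

## Expression and the two network models

Counts normalise to RP10M (`raw × 10⁷ / library total`), log2 views add a
pseudocount of 1, and Z-scores standardise rows with the sample standard
deviation (constant rows map to zero with a warning). Features enter
differential testing only with RP10M > 10 in at least one library (the
group-wise reading is available via `rp10m_gate_mode`). The fold change is
`log2((mean RP10M_rep + 0.5)/(mean RP10M_veg + 0.5))` — the 0.5
pseudocount handles zeros, on which the published methods are silent — and
the p-value is a two-sided exact binomial test of pooled raw counts
against the pooled library-size proportion, with Benjamini–Hochberg FDR.
This test is intentionally simple and exactly reproducible; it does not
model biological overdispersion, so its p-values are anti-conservative for
noisy features. The design accepts that: class-specific fold-change
thresholds (|log2FC| ≥ 2 for miRNA, ≥ 1 for PHAS and mRNA, both with FDR
≤ 0.05) do the heavy lifting, and the acceptance standard is recovery of
planted fold changes, not numerical equality with any particular
negative-binomial engine.

Triples join trigger assignments with accepted miRNA→mRNA targets;
phasiRNA→mRNA targets of the triggered locus annotate `phasi_support`.
Features that never reach the FDR cut-off contribute a fold change of 0 —
"not differentially expressed" — which automatically satisfies the Model-1
PHAS clause and fails the miRNA/mRNA magnitude clauses. Classification
applies the printed inequalities with strict comparisons throughout; a
missing PHAS locus makes the Model-1 clause vacuously true and Model 2
impossible, and the two models are provably exclusive (the grid test
asserts it over 729 sign/magnitude combinations). Trigger (miRNA→PHAS)
edges are filtered at Pearson `r > 0.7` on log2 RP10M — the published text
applies the correlation to triggering relationships — while miRNA→mRNA
edges are annotated with `r` but not filtered; Spearman is available
(`cor_method`).

## The synthetic study

`simulate_srna_study()` is a first-class module, not a fixture: it plants
a 50-kb genome with 6 MIR hairpins and 8 PHAS loci (two 24-nt), 12
transcripts of 600 nt, and 8 libraries (4 reproductive, 4 vegetative,
about 200k reads in total) — a desk-scale stand-in for the 34-library,
10-Gb study design it emulates. Hairpins are written so the duplex
criteria hold by construction; PHAS loci carry a perfectly complementary
trigger site whose predicted cleavage coordinate *is* the first phased
position; phased reads appear on both strands under the +2 overhang
convention. Counts are negative-binomial (dispersion 0.1) around
tissue-group means encoding planted log2 fold changes of ±4 for the
regulatory miRNA/mRNA pairs and +2 for the Model-2 PHAS locus; a
vegetative-preferred miRNA (−4) and cambium-type vegetative-preferred
loci (−2, including the 24-nt loci, mirroring the cambium expression of
24-nt phasiRNAs in the real tissue panel) balance the two directions so
that library totals — and hence RP10M — stay comparable between groups,
as they do in real sequencing designs; an all-up design would otherwise
leak a composition bias into every fold change. Background
noise species are uniform over the genome at a planted:noise abundance
ratio of about 5:1, and two rRNA-like contaminant species exercise the
blacklist. The planted regulatory truth contains exactly one Model-2
triple (miRNA ↑, PHAS ↑, CHS-like mRNA ↓, with a phasiRNA of the locus
hitting the same transcript), one triggered Model-1 triple (flat PHAS),
and one trigger-less Model-1 pair, plus decoy loci and flat features.

What passing these tests shows: every statistical primitive equals an
independent brute-force oracle; every printed threshold acts with its
printed strictness; and under the planted conditions the pipeline recovers
the truth with recall ≥ 0.95 and precision 1.0 across 20 seeded
replicates. What it does not show: performance on real genomes with
repeat-driven multi-mapping, isomiR clouds, RNA secondary-structure
effects on folding and target accessibility, sequencing-error profiles, or
batch structure across heterogeneous public libraries — the synthetic
generator models none of these beyond uniform noise and NB overdispersion.

## Problem sizes and determinism

The seeded recovery suites run 20 replicates of a scaled-down study
(20-kb genome, 4 MIR, 4 PHAS, 6 transcripts, unit depth); the end-to-end
checks run the full default study once. These sizes are the package's
chosen test design: large enough that every stage sees non-trivial input,
small enough that the whole suite is a coffee-break run. All generators
draw from R's integer RNG streams only, so identical seeds give identical
studies across platforms, and the pipeline itself is deterministic —
identical inputs and configuration give identical outputs, which the suite
asserts by running it twice.
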