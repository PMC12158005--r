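# phasnet

Plant small-RNA annotation and miRNA–phasiRNA–mRNA network inference in R.

## The problem

In plants, two classes of small RNAs dominate post-transcriptional
regulation: microRNAs (miRNAs), excised from fold-back precursors as a
mature/star duplex, and phased secondary siRNAs (phasiRNAs), produced in
21- or 24-nt increments from *PHAS* precursor loci after a trigger miRNA
cleaves the transcript and sets the phase register. Annotating both
classes from sRNA-seq data, identifying which miRNAs trigger which *PHAS*
loci, predicting the targets of both, validating cleavage with degradome
(PARE) data, and stitching the results into a regulatory network is the
standard analysis arc of gymnosperm and angiosperm sRNA studies — `phasnet`
implements that entire arc as composable, tested R functions, modelled on
the analysis of the *Ginkgo biloba* reproductive-vs-vegetative sRNA
dataset. It targets bioinformaticians who want each statistical step to be
inspectable and reproducible rather than buried in a monolithic pipeline.

## The statistics at the core

* **MIR locus calling.** Aligned tag stacks (all placements with ≤ 2
  mismatches, tags with > 20 genomic hits discarded) are clustered; a
  locus is accepted when the mature (20–22 nt) and its star — paired under
  the Dicer duplex register with 2-nt 3′ overhangs, spacing 5–300 nt —
  together account for ≥ 75 % of locus reads.
* **PHAS detection.** For a window of 11 phasing cycles, with `N = 2 ×`
  window length eligible 5′-end positions on both strands, `m = 2 ×`
  cycles of them in a candidate register, `n` occupied positions and `k`
  occupied in register, the phasing p-value is the hypergeometric tail
  `P(X ≥ k)`, and the phasing score is
  `(k − 2) · ln(1 + 10 P/(1 + U))` with `P`/`U` the in-/out-of-register
  abundances. A locus needs dominant length = period (21 or 24 nt), span
  > 100 bp, phased fraction > 30 %, `p < 0.001` and score > 10. Minus-strand
  reads phase through the +2 overhang convention.
* **Triggers and targets.** Trigger miRNAs are assigned by penalty
  alignment (Allen convention: mismatch 1, G:U 0.5, gap 2, doubled at
  positions 2–13) against the locus ± 200 bp, penalty ≤ 5; targets are
  accepted when Allen score < 7 **and** MFE ratio > 0.65 on one alignment
  engine. Cleavage is predicted opposite sRNA positions 10–11.
* **Degradome validation.** 5′-end pileups are categorised 0–4
  CleaveLand-style; categories 0–3 with penalty ≤ 6 validate a site.
* **Network models.** With log2 fold changes (reproductive vs vegetative;
  RP10M-normalised, exact binomial test on pooled counts, BH FDR ≤ 0.05),
  a miRNA–PHAS–mRNA triple is **Model 1** (miRNA-only) when
  `FC_mi·FC_mrna < 0`, `|FC_mi| > 1`, `|FC_mrna| > 1` and the PHAS locus is
  flat or discordant, and **Model 2** (miRNA + phasiRNA co-regulation) when
  the PHAS locus instead moves with the miRNA (`FC_mi·FC_phas > 0`,
  `|FC_phas| > 1`). Trigger edges are kept at correlation `r > 0.7`.

## Worked example

Everything below runs offline: the synthetic-data generator plants a full
study — genome, MIR hairpins, PHAS loci with trigger sites, transcripts
with target sites, degradome peaks, multi-tissue libraries — with
machine-readable truth.

```r
library(phasnet)

study <- simulate_srna_study(seed = 7)
res <- run_pipeline(study)

res$mir_unique[, c("locus_id", "family", "novel", "duplex_fraction")]
#> 1 MIR001  miR159 FALSE  0.886
#> 2 MIR003  miRN1  TRUE   0.972
#> ...  (6 loci: 2 known families, 4 novel)

res$phas[, c("locus_id", "period", "p_value", "phasing_score",
             "phased_fraction")]
#> PHAS21-1 ... 4.95e-33  103.  0.958
#> ...  (6 x 21-nt and 2 x 24-nt loci, all p < 0.001, score > 10)

res$triggers
#> mirna_id phas_id  penalty strand cleavage_coord in_register
#> MIR007   PHAS21-5       0 +               35045 TRUE
#> MIR001   PHAS21-6       0 +               43862 TRUE

tidy(res$network)[, c("mirna_id", "phas_id", "mrna_id", "model")]
#> MIR001 PHAS21-6 mrna_1 model2    <- miRNA + phasiRNA co-regulation
#> MIR007 PHAS21-5 mrna_2 model1
#> MIR009 <NA>     mrna_3 model1
```

The two trigger assignments recover the planted miRNA→PHAS pairs with
penalty 0 at the planted cleavage register; the single `model2` triple is
the planted one (up-regulated miRNA, co-up-regulated PHAS locus, repressed
CHS-like transcript, with a phasiRNA of the locus hitting the same mRNA,
degradome-validated at category ≤ 3).

Plots: `plot_phasing(res$phas[1, ])`, `plot_tplot(res$deg_profile,
"mrna_1", cleavage_pos = 251)`, `autoplot(res$de$mirna)` (volcano),
`autoplot(res$network)`.

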