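---
title: "Methods: post-discovery miRNA analysis with mirpost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-discovery miRNA analysis with mirpost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpost)
```

# Scope

`mirpost` implements the downstream half of a miRNA discovery study in a
newly sequenced genome: everything that happens *after* a discovery tool
(a miRDeep2-style scorer) and the alignment programs have produced their
tabular outputs. The package takes candidate hairpin precursors with their
read stacks and BLAST evidence, and carries them through validation and
annotation, gene-cluster detection, read-count normalization,
reference-gene selection for RT-qPCR, and comparative-Ct differential
expression. Running the aligners themselves, RNA secondary-structure
prediction and official nomenclature assignment are out of scope.

# Candidate classification

Candidates are classified independently of each other, in a fixed order of
rules; the first decisive rule wins and is recorded as the rejection
reason:

1. **Score cutoff.** Discovery scores must be *strictly above* the cutoff.
   The cutoff is a user parameter (default 4 in the configuration): the
   appropriate value comes from the discovery tool's signal-to-noise table
   (the score at which real-genome candidates outnumber permuted-genome
   candidates about 30:1), which this package does not recompute.
2. **Conserved annotation.** A BLAST match to a known stem-loop with
   E-value ≤ 1e-06 (boundary included) makes the candidate a conserved
   ortholog, annotated by the best hit — lowest E-value, ties broken by
   highest bit score, then alphabetical subject id, so annotation is
   deterministic.
3. **Other small RNAs.** A significant match to an Rfam-style small-RNA
   family database removes the candidate (it is likely a tRNA/snoRNA
   fragment or similar).
4. **Repeats.** A candidate with significant genome hits at more than
   `max_loci` distinct loci is treated as repeat-derived. Distinct loci are
   counted after merging overlapping hit intervals on the same subject and
   strand, so HSP fragments of one locus count once. The default is
   `max_loci = 5`; a stricter preset of 50 is sometimes used for highly
   repetitive assemblies, and both are exposed in the configuration because
   the field uses both conventions.
5. **Novel validation.** The remaining candidates must show (i) reads in at
   least two independent libraries, (ii) pooled perfectly matching reads
   strictly greater than five on *each* arm (so five reads fail, six pass),
   and (iii) consistent processing of the mature 5′ end. Criterion (iii) is
   qualitative in common practice; we quantify it as: on each arm, the
   modal read start offset must carry at least 90% of that arm's reads
   (`consistency_frac = 0.9`). This tolerates rare off-by-one reads while
   rejecting candidates with diffuse 5′ ends, which are the hallmark of
   degradation products. Arm read counts are pooled across libraries
   because per-library thresholds would penalize tissue-restricted miRNAs.

Arm dominance is the arm with the larger pooled read count; exact ties are
called codominant. Mature sequences of accepted genes are collapsed by
exact string identity — gene family members often share identical matures —
giving the unique mature set used for quantification.

# Gene clusters

Two or more genes on the same contig and strand whose neighbour gap is
strictly less than 10 kb (the miRBase convention) form a cluster, with
transitive chaining, so a cluster can span more than 10 kb end to end. The
gap is measured edge to edge (`max(0, next_start − prev_end − 1)` on
1-based inclusive coordinates); whether the convention is edge-to-edge or
start-to-start is not settled, so `gap_mode = "start"` is available. The
implementation reduces intervals with `GenomicRanges`; the test suite
checks it against an all-pairs connected-components oracle on random
layouts.

# Quantification and RSD screening

Reads count toward a mature miRNA only on exact string match (no
mismatches, no indels — isomiR analysis is a non-goal), and reads shorter
than 18 nt are discarded. Because the mature set is collapsed to unique
strings, a read can match at most one entry, and a mature shared by
several gene copies is counted once: counts are per mature sequence, not
per locus.

Normalized expression is `count / total × 10⁴`, where the total is the
number of miRNA-matching reads in that library; with this denominator
every column of the normalized matrix sums to 10⁴ exactly. No
TMM/DESeq-style size factors are attempted — the per-10⁴ scale is the
convention this analysis inherits.

Cross-tissue stability is screened by the relative standard deviation
(RSD = sd/mean, n−1 denominator, scale-free); reference candidates are
taken greedily in ascending RSD while skipping any miRNA that shares a
gene family or cluster with one already chosen, since co-regulated genes
would validate each other trivially. Tissue-enriched candidates are ranked
by the largest per-tissue mean divided by the mean of the remaining
tissues, with zeros smoothed to half a read on the count scale.

# Reference-gene stability (model-based)

The RT-qPCR validation step ranks candidate reference genes by a
NormFinder-style variance decomposition, re-implemented from the
underlying random-effects model rather than wrapped from any external
tool. Ct values are first linearized as `2^(C − Ct)` (C = the matrix
maximum; the constant shifts the log scale and cancels) and log2 is taken
internally, so the model works on the cycle scale.

For gene *i*, tissue group *g*, sample *j*:

y_igj = μ_i + κ_gj + d_ig + ε_igj,  ε_igj ~ N(0, σ²_ig)

where κ_gj is a sample effect (removed by centering each sample across the
K genes), d_ig are gene-by-group differences summing to zero over genes
and over groups, and σ²_ig is the intra-group noise. The estimators are
method-of-moments:

* the per-sample centering leaks 1/K of every gene's noise into each
  residual; with v_ig the residual variance, E[v_ig] = σ²_ig(1 − 2/K) +
  S_g/K², which is solved for σ̂²_ig using Ŝ_g = K/(K−1)·Σ v_ig and clamped
  at zero (hence at least three genes are required);
* d̂_ig is the group mean of the centered residuals, centered per gene
  across groups; its sampling variance is σ̂²_ig/n_g;
* the inter-group variance component is γ̂² = max(0, (Σ d̂² − Σ σ̂²/n_g) /
  ((K−1)(G−1))) — the sampling-error correction subtracts the intra-group
  variance over the group size, and negative method-of-moments estimates
  are clamped at zero, standard practice for variance components.

The stability value of a gene is the group average of
|d̂_ig|·w + sqrt((σ̂²_ig/n_g)·w) with the shrinkage w = γ̂²/(γ̂² + σ̂²_ig/n_g):
group differences are shrunk toward zero in proportion to how much of
their spread sampling noise explains. Lower is more stable. When γ̂² = 0 the
inter-group term vanishes identically and the value reduces to the
sampling uncertainty of the group means, which preserves the ranking by
noise. The decomposition is invariant to global Ct shifts and to group
relabeling, and log base 2 is immaterial for the ranking.

For the best two-gene combination every unordered pair is evaluated: the
pair's difference terms are the average of the two genes' terms (opposite
biases cancel — the reason a pair can beat every single gene) and its
intra-group variance is the variance of the average, (σ²_a + σ²_b)/4. The
pair is reported alongside the best single gene; neither is guaranteed to
beat the other.

Amplification efficiency is not modelled: poorly efficient assays (the
classic U6 problem) should be excluded before stability ranking, so the
module accepts a pre-filtered candidate list.

# Differential expression by comparative Ct

Per sample, ΔCt = target Ct − the geometric mean of the reference-gene
Cts. The geometric mean is applied to the Ct values themselves, as
written in the convention this follows; since Cts are already log-scale an
arithmetic-mean mode is provided and gives very similar values for
reference genes of similar level.

The initial target tissue(s) come from the sequencing screen. Because a
miRNA may be enriched in more tissues than first suspected, any reference
tissue whose ΔCt values overlap the target range is promoted to target and
the check iterates to a fixed point. The default quantitative rule is:
promote a reference tissue whose median ΔCt is below the maximum ΔCt
observed in the current target group ("median_below_max"); a stricter
median-vs-median rule is configurable since the underlying practice is a
visual inspection with no unique formalization. A gene with no enrichment
anywhere overlaps everywhere, which would promote every tissue and leave
no reference group; `assign_target_tissues()` treats that as an error, and
`de_test()` falls back to the initial target set and flags the row
(`all_tissues_overlap`), which is the conservative comparison for a flat
profile.

Groups are compared by Welch's unequal-variance t-test (two-sided,
Satterthwaite df; the degenerate constant-equal case is p = 1 by
convention). With 76 tests at α = 0.05 the Bonferroni-corrected threshold
is 0.05/76 ≈ 6.6e-04, applied as a strict inequality. The relative
increase is 2^ΔΔCt with ΔΔCt = mean reference ΔCt − mean target ΔCt,
assuming 100% efficiency. Sequencing-side fold estimates (target-mean over
reference-mean of normalized counts) are compared with the qPCR folds by
product-moment correlation on the log2 scale — folds are ratios, so the
log scale is the natural one; raw and rank variants are configurable.
Only miRNAs with nonzero normalized counts in every library enter the
correlation, since a zero makes the sequencing ratio undefined.

# The synthetic study

All tests run on seeded synthetic data shaped like the study design the
pipeline assumes: eight deep-sequencing libraries (one per organ) and a
nine-tissue × eight-individual qPCR design.

* **Candidates** (`simulate_candidates()`): 50 candidates by default — 20
  conserved, 10 valid novels, and 20 negatives each violating exactly one
  rule, so the classification chain can be scored exactly. A few conserved
  genes are planted in clusters of 3, 3 and 2 with 2–6 kb gaps, mirroring
  the fact that a share of real miRNA genes is polycistronic.
* **Counts** (`simulate_counts()`): negative-binomial counts (dispersion
  `size = 10`, the overdispersion scale typical of small-RNA libraries)
  around log-normal relative abundances, with planted tissue enrichment
  (default 8-fold) and library sizes spanning 2×10⁵–10⁶ — a five-fold
  spread, scaled down from the millions of reads of real libraries so the
  suite runs in seconds; the spread, not the absolute depth, is what the
  normalization must absorb.
* **Ct values** (`simulate_ct()`, `simulate_qpcr_run()`): Gaussian on the
  cycle scale — gene baseline + per-tissue effect (inter-group spread) +
  individual noise (intra-group σ, default 0.5 cycles for targets, 0.3 for
  reference genes), with planted target-tissue shifts in cycles. A DE run
  uses 8 target samples and 4 individuals from each of 7 reference
  tissues (28 reference samples), inside the 20–32 envelope of the design.

What the simulation does *not* emulate: sequencing error and adapters,
isomiR heterogeneity, amplification-efficiency differences between assays,
cross-hybridization, and correlated individual effects across tissues.
Passing tests therefore demonstrate that the algorithms implement their
definitions correctly and are well calibrated under the assumed noise
models — not that those models capture every property of real libraries.

# Problem sizes and determinism

The shipped test suite and the acceptance script use: 50-candidate
classification runs, 200 random layouts for the cluster oracle, 200 seeded
replicates for reference-gene recovery, and 200 + 200 replicates for DE
power and false-positive calibration; these sizes give binomial standard
errors of about 1.5 percentage points on the reported rates while keeping
a full run within a couple of minutes on one CPU. Every stochastic step
takes an explicit integer seed, and equal seeds give byte-identical
outputs, including the on-disk files written by `write_simulation()`.

# Known limitations

* The classification chain trusts the E-values in the hit tables; it does
  not re-BLAST or verify alignment coordinates.
* The repeat filter's locus merging assumes hits come from one assembly;
  mixed-assembly hit files would need pre-filtering.
* The stability model assumes no missing Ct values and at least two
  samples per group; single-sample groups are refused rather than imputed.
* The promotion rule formalizes a visual-inspection step; with a different
  rule the target set for borderline miRNAs can differ, which is why the
  rule is configurable and recorded in the DE report.
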