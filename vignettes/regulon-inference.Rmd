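---
title: "Inferring combinatorial TF dependencies from factorial deletion transcriptomes"
author: "facreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring combinatorial TF dependencies from factorial deletion transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*Aspergillus niger* degrades pectin with a battery of enzymes whose genes
are activated by (at least) three transcription factors: GaaR (responding
to D-galacturonic acid), AraR (L-arabinose) and RhaR (L-rhamnose). A
single-knockout experiment can say that a gene needs a TF; it cannot say
*how* several TFs combine. A factorial deletion panel can: with all
8 = 2³ combinations of the three deletions profiled by RNA-seq, each
gene's pattern of regulation across the 7 mutants is a truth table over
the deletion indicators, and the combinatorial logic (single dependence,
AND, OR, mixed forms) can be read off directly.

`facreg` implements that inference chain as a reusable, tested pipeline:

1. **quantify** — FPKM from a gene × sample count matrix, and
   expression-status bands;
2. **diffexp** — a self-contained negative-binomial Wald test of each
   mutant against the reference, per timepoint;
3. **depclass** — the core step: per-genotype regulation calls to a
   minimal monotone Boolean dependency expression, predominant-activator
   attribution, Venn partition, temporal switches;
4. **clustering** — deterministic complete-linkage clustering of the
   averaged log expression matrix;
5. **motifs** — promoter motif machinery (IUPAC and PWM scanning with
   exact p-values, ZOOPS-EM discovery, enrichment, conservation);
6. **synthgen** — a generator of factorial-deletion transcriptomes and
   promoter sets with known ground truth, so every stage is testable
   without external data.

## Quantification

FPKM is the classical unit:
$$\mathrm{FPKM}_{gs} = \frac{c_{gs}}{(\ell_g/10^3)\,(N_s/10^6)},$$
with $c_{gs}$ the count, $\ell_g$ the gene length in bp and $N_s$ the
column sum of the supplied matrix ("total mapped fragments" — read
alignment and multi-mapper removal happen upstream of this package).
Per sample $\sum_g \mathrm{FPKM}_{gs}\,\ell_g/10^3 = 10^6$ exactly, a
conservation law the tests assert to $10^{-6}$.

Expression status is anchored on the reference strain's replicate-mean
FPKM per timepoint: below 1, *not expressed* (a strict `<`); from 1 to
20 inclusive, *lowly expressed*; above 20, *expressed*. Both band edges
class as *low*; the status of mutants never feeds this call, which keeps
the bookkeeping (regulated + not regulated + not expressed = panel size)
reproducible.

Heatmap matrices average replicates per genotype × timepoint and take
$\log_2(\text{mean FPKM} + 1)$ (the base is configurable).

## Differential expression

Normalization is median-of-ratios: each sample's factor is the median,
over genes with no zero count anywhere, of the count over the gene's
geometric mean. The test is a gene-wise NB Wald test on normalized
counts:

* $\log_2\mathrm{FC} = \log_2\frac{\bar y_{mut}+0.5}{\bar y_{ref}+0.5}$
  with a 0.5 pseudocount;
* gene dispersion $\alpha$ by method of moments
  ($\alpha = (s^2-\bar y)/\bar y^2$ per group), pooled across the two
  groups with degrees-of-freedom weights and floored at $10^{-8}$;
* the delta-method variance of each group mean,
  $(\bar y + \alpha\bar y^2)/n$, is never taken below the group's
  empirical variance $s^2/n$. This floor is the package's own choice: a
  moment-based Wald test with two to five replicates underestimates its
  standard error often enough to be visibly anticonservative (measured
  null rejection 0.087 at 5 vs 5 without the floor, 0.068 with it), and
  the floor buys calibration without the severe power cost that a
  $t$-reference would impose at two replicates;
* $z = \log_2\mathrm{FC}/SE$, two-sided normal $p$; genes with zero
  counts in both groups report $p = 1$.

Calls use the experiment's published cut-offs: Benjamini–Hochberg within each contrast
(mutant × timepoint), *down* iff fold change strictly exceeds 1.5
downward and adjusted $p \le 0.05$ (inclusive), *up* symmetric. Gene
results from this test are not expected to be bit-identical to any
external DE package; the cut-off semantics are what the downstream logic
consumes.

## Dependency classification

For a gene, timepoint and direction, the seven calls form a bit pattern
over the mutants $\{G, A, R, AG, AR, GR, AGR\}$. With the reference
fixed at "not regulated", a pattern is consistent with activator logic
only if it is *upward-closed*: deleting more TFs can only keep or extend
the loss of expression. For upward-closed patterns the unique minimal
monotone DNF is the disjunction of the minimal true deletion sets — e.g.
regulated exactly in $\{AG, AGR\}$ gives `G&A` (class *and*); regulated
everywhere except $R$ gives `G|A` (class *or*); regulated in
$\{AG, GR, AGR\}$ gives `(G&A)|(G&R)` (class *mixed*). Patterns that are
not upward-closed are labelled `complex` rather than forced into a DNF.
There are exactly 19 realizable monotone functions (the 20 monotone
Boolean functions on three variables minus constant-TRUE, impossible
because the reference is never regulated against itself); tests
enumerate all of them and verify soundness and minimality against a
brute-force search.

The *predominant* activator of a multi-TF gene is the one whose single
deletion moves expression furthest in the call's direction; TFs within
0.1 log2 units (configurable — no published numeric rule exists) of the
extreme are reported as a tie. For AND-class genes both single mutants
are weak by construction, so a tie or an empty set is the documented
outcome, not an error.

Venn partitioning puts a gene in circle X iff literal X appears in its
expression; `none` and `complex` genes fall into a separate bucket so
region counts always sum to the classified genes. Temporal switches
compare canonicalized expressions (literals and clauses sorted) between
timepoints, so `A|G` versus `G|A` is not a switch.

Up-regulation (e.g. the antagonistic induction of xylanolytic genes when
*gaaR* is deleted) is classified by the same machinery with
`direction = "up"` and reported separately.

## Clustering

Complete linkage on Euclidean row distances of the averaged-log matrix,
the parameters used for the published heatmaps. The agglomeration is
implemented in-package so tie-breaking is fully specified: among pairs at
the minimal distance, the pair with the lexicographically smallest
(min original row index, max original row index) merges first, making
results invariant to row order up to labels. Rows are not scaled or
centred (the heatmaps cluster logged FPKM+1 values directly), and only
rows are clustered. The object inherits from `hclust`, so `cutree()`,
`plot()` and `cophenetic()` work.

## Motif machinery

**Coordinates.** Promoters are the 1,000 bp immediately upstream of the
start codon. A hit's `upstream_position` is the distance from the start
codon to the *leftmost* base of the matched window on the forward strand,
i.e. $L - s + 1$ for leftmost 1-based coordinate $s$; strand is reported
separately, and minus-strand matches are reported in motif orientation.
Published motif tables state positions "with respect to the start codon"
without fixing the anchor base; this one convention is used throughout.

**IUPAC scanning** reports every overlapping exact match on both strands;
`N` never matches. **PWM scanning** scores windows by log2 odds against a
0-order background and converts scores to exact p-values by dynamic
programming over the score distribution after discretizing log-odds to
$10^{-3}$ bits — fine enough that tests demand equality with exhaustive
enumeration to $10^{-12}$ for widths up to 8. Site calling uses
$p < 10^{-4}$ by default, the published site threshold. Note that a PWM
built *from a degenerate consensus alone* (uniform within allowed sets)
has a best-window p-value of $5.5\times10^{-4}$ for a 7-mer with two
3-letter positions — above that threshold; meaningful $p<10^{-4}$
scanning needs a site-trained matrix (e.g. from discovery), which is why
both scanners are provided.

**ZOOPS-EM discovery.** Each sequence carries zero or one occurrence of
the motif; EM alternates site posteriors with re-estimation of the letter
probabilities (pseudocount 0.25) and the site prior γ. The observed-data
log likelihood is non-decreasing — asserted on every run. Widths 6–10
are searched by default. Seeding is two-staged: candidate w-mers are
shortlisted by their Hamming-≤1 *sequence support* (a degenerate motif
spreads its instances over many distinct w-mers, so raw frequency cannot
find it), re-ranked by the likelihood reached after two EM iterations,
and the best eight run to convergence. Motifs are ranked by the ZOOPS
log-likelihood ratio with a configurable floor — a deliberate stand-in
for a MEME-style E-value, which is not re-derived. Two consequences are
documented rather than hidden: the raw LLR grows with width, so
cross-width comparison should inspect the per-width motifs; and a
7-mer in 1-kb sequences sits near the ZOOPS detection limit (information
content ≈ 11 bits against a position entropy of ≈ 10 bits), which is why
the seed search needs to be generous. Discovery uses the forward strand;
scanning covers both.

**Enrichment** builds the 2×2 presence table (target set versus
background or genome-wide set), reports proportions, the cross-product
odds ratio with a Haldane 0.5 correction when any cell is zero, and a
two-sided Fisher exact p. **Conservation** scans each species' ortholog
promoter set and reports the fraction with a hit plus a majority flag.

## The synthetic generator

The generator emulates the experimental design so the whole chain can be
validated against known truth: 8 genotypes × 2 timepoints × 2 replicates;
NB counts with $\mathrm{Var} = \mu + \alpha\mu^2$ ($\alpha = 0$ gives
Poisson); per-gene monotone DNF dependencies whose satisfied clauses
subtract their effects on the log2 scale; TF genes emitted as hard zeros
in every genotype deleting them (their expression is abolished in the
corresponding mutants, not merely reduced); promoters with planted,
exactly recoverable motif instances.

Defaults, and why:

* **class mix** `none .60, single .20, and .08, or .08, mixed .04`. The
  simulated object stands in for a transcriptome, most of which is not
  controlled by these three TFs; a majority of unchanged genes is also
  the stated assumption of median-of-ratios normalization, which breaks
  down if most genes move (as they would in a triple mutant of a
  panel-only simulation).
* **baselines** — dependent genes draw reference means of $2^7$–$2^{11}$
  counts, unregulated genes $2^3$–$2^9$. The regulated pectinolytic
  genes are the induced, clearly expressed ones, while genes escaping
  regulation are predominantly in the lowly expressed band.
* **effects** — uniform 2–6 log2 units per clause (4- to 64-fold).
  Published reductions for clearly dependent genes in this system range
  from a few-fold to several-hundred-fold; the 2 log2 floor is the
  boundary of what a duplicate design can call reliably.
* **dispersion 0.05**, typical for technical-replicate-like duplicate
  cultures; **library depth factors** log-uniform in [0.8, 1.25] to
  exercise normalization without dominating the signal.

What the generator does **not** emulate: read-level artifacts (it starts
at counts), GC or positional bias, time-course autocorrelation (the two
timepoints share parameters), cross-regulation between the TFs (the
documented *gaaR* reduction in Δ*araR* is deliberately out of scope), or
promoter structure beyond an i.i.d. background with planted sites.
Passing end-to-end tests therefore demonstrates that the inference chain
is correct *under its stated model*; on real data, cross-regulation,
batch structure and alignment artifacts can produce `complex` patterns
and imperfect recovery that the synthetic conditions do not show.

## Validation sizes and determinism

All stochastic stages take explicit integer seeds and restore the RNG
state; identical inputs and seeds give byte-identical outputs, which the
tests assert at the file level. The validation suite uses problem sizes
chosen to make the checks sharp but quick: 400-gene models for
end-to-end recovery (≈ 160 dependent genes, both timepoints), 10,000
null genes for calibration, 4,000 for power, 1,000 promoters of 1 kb for
scanner-oracle equivalence, and the 34-promoter (28 planted) fixture for
discovery. Under those conditions the chain recovers ≥ 95% of
ground-truth dependency expressions, detects abolished TF genes at 100%,
and keeps the null rejection rate of the DE test within [0.03, 0.08].

## Known limitations

* The DE test has no dispersion shrinkage across genes, no GLM
  covariates and no outlier handling; with two replicates its power at
  effects below ~4-fold is limited, and genes near that boundary are the
  main source of imperfect recovery.
* The minimal-DNF classifier is exact but brittle to single wrong calls:
  one false positive in a double mutant converts a clean `single` gene
  into `mixed` or `complex`. This is a property of the inference problem
  itself, not of the implementation; a factorial design of this size (7 contrasts
  per timepoint) simply has no redundancy to absorb call errors.
* ZOOPS discovery ranks by raw LLR, not an E-value; very wide, low
  information motifs can outrank compact ones across widths.
* Size factors inherit the median-of-ratios assumption; simulations (or
  data) in which most genes respond will bias multi-deletion contrasts.
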