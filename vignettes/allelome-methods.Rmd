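---
title: "Methods: allele-specific expression atlases from reciprocal hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific expression atlases from reciprocal hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allelome)
library(dplyr)
```

## The problem

In an F1 hybrid between two inbred mouse strains (call them B, the
reference-like strain, and C, the variant-carrying strain), every autosomal
gene has one allele from each parent, distinguishable wherever the strains
carry sequence variants. Two biological mechanisms produce unequal allelic
expression: **genomic imprinting** (epigenetic silencing of one *parental*
allele) and **strain effects** (cis-regulatory differences between the
*strains*). A single cross cannot tell them apart: in a B-dam x C-sire
hybrid ("BC"), "mostly-B expression" is equally consistent with maternal
imprinting and with a strong B enhancer. The **reciprocal cross** ("CB",
C dam x B sire) breaks the confound: a parent-of-origin effect follows the
dam and flips which strain is overexpressed, whereas a strain effect stays
with the strain.

`allelome` implements this design end to end: a strain-aware ("diploid")
transcript reference, read-to-allele assignment at diagnostic positions,
a tolerance-filtered resampling test of allelic imbalance in parental and
strain orientation, reciprocal-concordant classification into
maternal / paternal / strain-biased / biallelic states, atlas assembly
across cell types and developmental stages, and candidate-gene screens
over differential-expression tables. A synthetic-data generator with
planted truth makes every step testable against known answers.

## The statistical model

### Oriented fractions and the sign-flip test

For gene $g$ in one condition (cell type x stage) with replicates
$i = 1..n$ spanning both crosses, let $b_i$ and $c_i$ be the reads assigned
to alleles B and C. The **oriented fraction** is

- parental orientation: $f_i = b_i/(b_i + c_i)$ in BC replicates and
  $c_i/(b_i + c_i)$ in CB replicates (the *maternal* fraction);
- strain orientation: $f_i = b_i/(b_i + c_i)$ in every replicate.

The test statistic is the unweighted mean deviation
$S = \frac{1}{n}\sum_i (f_i - \tfrac12)$. Under the null of balanced
expression the per-replicate deviations are symmetric about zero and
exchangeable in sign, so the null distribution is built by **sign-flip
resampling**: $S^* = \frac{1}{n}\sum_i \epsilon_i (f_i - \tfrac12)$ with
$\epsilon_i$ i.i.d. uniform on $\{-1, +1\}$, and

$$p = \frac{1 + \#\{|S^*| \ge |S|\}}{R + 1}$$

over $R$ resamples, which respects the permutation floor
$p \ge 1/(R+1)$. We use the replicate-*mean* statistic rather than pooled
counts because replicate-level exchangeability is what justifies the
sign-flip null; pooled fractions ($\sum$ maternal / $\sum$ total) are still
reported for display. This is an explicit, oracle-checkable "ISoLDE-style"
test, not a byte-level reimplementation of any external tool.

**Exact enumeration.** With few replicates the null is tiny: at $n = 8$
there are only $2^8 = 256$ sign assignments. Whenever $2^n \le R$ the
implementation enumerates them all (`method = "auto"` in
`sign_flip_test()`), making the p-value exact and deterministic; Monte-Carlo
resampling remains available (`method = "resample"`) and is validated
against the exhaustive enumeration in the test suite. The exact null is
discrete: the smallest achievable two-sided p at $n = 8$ is
$2/256 \approx 0.0078$. This matters downstream — under
Benjamini–Hochberg over $m$ genes at level $\alpha$, an effect family
smaller than roughly $\alpha\, m / p_{\min}$ genes (about 310 of 2,000 at
$\alpha = 0.05$) can never clear the adjusted threshold, however strong the
effects. That is a property of 8-replicate designs, not of this
implementation; the gene-level strain screen below intentionally does not
gate on significance for this reason, and detection of small effect
families improves with replicate number, not resamples.

### Normalisation, filtering, multiplicity

- **Size factors** are median-of-ratios: per sample, the median over genes
  (restricted to genes positive in every sample) of count / per-gene
  geometric mean. The implementation is validated against the DESeq2
  estimator in the test suite.
- **RPKM** $= 10^9 \cdot \text{count} / (\text{length} \cdot
  \text{library size})$; condition-level RPKM is the mean over that
  condition's replicates. The expression floor everywhere is RPKM > 1.
- The **tolerance filter** is the pre-test gate: a gene x condition passes
  when at least $\max(1, \lceil n(1 - t/100)\rceil)$ of its $n$ replicates
  carry $\ge$ 10 reads. Tolerance $t = 0$ demands every replicate,
  $t = 100$ just one; the default 50 balances the two extremes.
  Replicates with zero total are dropped from the test (fractions are
  undefined at 0; no pseudocounts), and a gene x condition with fewer than
  `min_informative_reps = 2` informative replicates is flagged untestable
  (`p = NA`) rather than silently assigned $p = 1$.
- **BH adjustment** is applied within each condition x orientation, because
  conditions are reported as independent panels of the atlas. The scope is
  a configuration choice, not a claim about the only valid scope.

### Classification and the concordance gate

Per gene x condition, with pooled maternal fraction $f_m$ and strain-B
fraction $f_B$:

| category | requires |
|---|---|
| `not_expressed` | condition RPKM $\le$ 1 |
| `maternal` | parental padj $\le 0.05$, $f_m \ge 0.7$, both crosses' $f_m > 0.5$ |
| `paternal` | parental padj $\le 0.05$, $f_m \le 0.2$, both crosses' $f_m < 0.5$ |
| `strain_B` / `strain_C` | strain padj $\le 0.05$, bias $|2f_B - 1| > 0.5$, both crosses on the same side |
| `inconclusive` | both orientations significant, or an orientation untestable |
| `biallelic` | everything else |

The monoallelic cutoffs 0.2 / 0.7 are deliberately asymmetric around 0.5
and applied literally to the maternal fraction (both configurable).
Significance *and* thresholds *and* reciprocal concordance must all hold:
thresholds alone would box noisy low-count ratios, significance alone would
flag modest imbalances far from monoallelic. The significance gate can be
disabled (`gate_significance = FALSE`) for threshold-only displays.

The **strain screen** is gene-level: a gene is flagged when it is expressed
(RPKM > 1) in at least 3 conditions and at least 3 of those show a bias
score $|2 f_B - 1| > 0.5$ (i.e. an allelic fraction outside
$[0.25, 0.75]$). Reading "expression bias > 0.5" on the raw fraction
would flag half of all genes, so the bias-score reading is used; the
number of bias-qualifying conditions mirrors the expression floor count
because the two criteria are coupled in the screen's definition, and both
are configurable.

### Swap symmetries

The design admits a $\mathbb{Z}_2 \times \mathbb{Z}_2$ symmetry group that
the implementation preserves exactly:

- swapping every sample's cross label (BC $\leftrightarrow$ CB) flips
  maternal $\leftrightarrow$ paternal calls and leaves strain calls
  untouched;
- swapping the two count layers *and* the cross labels leaves parental
  calls untouched and exchanges strain_B $\leftrightarrow$ strain_C
  (algebraically, the double swap maps the maternal fraction to itself,
  $f' = b/(b+c) = f$).

Because per-gene resampling seeds are derived from the global seed and the
gene identifier only — never from labels or counts — the symmetry holds
for p-values too, not just point estimates. Both relations are asserted in
the acceptance tests.

## The synthetic-data generator

`simulate_counts()` emulates the reciprocal-cross design: 2 crosses x 4
biological replicates x 6 sorted mammary cell populations (basal, luminal
progenitor, luminal differentiated, stromal, endothelial, adipocyte) x 10
stages (nulliparous; pregnancy P5.5/P9.5/P14.5; lactation L5/L10/L15;
involution I1/I6/I14), all configurable. Per gene x sample:

- the total count is negative-binomial around a log-normal gene mean
  (defaults: meanlog $= \log 100$, sdlog $= 1$, dispersion 0.1 — typical
  bulk RNA-seq magnitudes);
- the B-allele count is **beta-binomial** around the class fraction
  oriented by the cross, with intraclass correlation
  `bb_overdispersion`. The study design this mirrors reports no empirical
  overdispersion estimate, so the default $\rho = 0.02$ is a deliberate,
  prominently-exposed choice (mild extra-binomial replicate scatter); it
  reduces exactly to binomial at $\rho = 0$;
- planted classes: `biallelic` ($f_m = 0.5$), `maternal` / `paternal`
  (maternal fraction 0.9 / 0.1 by default), `strain_B` / `strain_C`
  (strain-B fraction 0.9 / 0.1), and `silent` (all counts exactly zero,
  giving an unambiguous below-threshold stratum for filter tests);
- an optional **alignment bias** $\delta$ maps a true B fraction $\mu$ to
  $\mu(1-\delta) / (\mu(1-\delta) + (1-\mu))$ *after* cross orientation,
  mimicking preferential read loss on the allele that differs most from
  the reference genome — the mechanism suspected when hybrid data show a
  systematic tilt toward the non-reference strain.

`simulate_transcriptome()` emits one random transcript per gene
(500–2,000 nt by default) with 5 planted diagnostic SNPs; indels are not
generated (keeping read-assignment truth unambiguous) although
`build_diploid()` fully supports them from input. `simulate_reads()` emits
exactly the requested number of reads per gene x sample x allele, uniform
starts, i.i.d. substitution errors, truth tags in the read names, and read
starts reported in reference transcript coordinates (alternate-haplotype
starts are mapped back through the coordinate map).

**What the simulator does not emulate** — and therefore what passing tests
do *not* establish about real data: mapping and multi-mapping artefacts
(reads are assigned by exact diagnostic-site comparison, standing in for
EM-based diploid quantification), isoform structure, paired ends,
quality-score-correlated errors, indel sequencing errors, batch and
animal effects beyond beta-binomial scatter, and genuine biological
variation in imprinting strength across conditions. Recovery rates on
synthetic data are a correctness check of the statistical machinery, not
an estimate of field performance.

## Numerical and degenerate-input choices

- Variants use 1-based VCF conventions with anchored-base indels;
  internal coordinate maps are built left-to-right and are strictly
  monotone off gaps; overlapping variants are rejected loudly rather than
  resolved by precedence.
- Read assignment scores matching bases at diagnostic positions only; a
  strictly higher score wins, ties and uninformative reads are
  `ambiguous`. The default counting policy discards ambiguous reads into
  their own layer (keeping counts integer); `split` divides them evenly
  for sensitivity analyses. `count_B + count_C + ambiguous` equals the
  reads assigned, asserted on every run.
- Tie comparison in the resampling test uses $|S^*| \ge |S| - 10^{-12}$ so
  floating-point noise cannot drop the identity assignment.
- Transcript-to-gene maps must be functions (a transcript may not feed two
  genes), preventing silent double counting.
- `n = 0` replicates fail the filter; `n_genes = 0` simulates empty
  tables; empty variant tables build an identity diploid.

## Problem sizes in the checks

The test suite and the acceptance script exercise the statistics at the
scales the analysis is designed for: 2,000 genes x 8 replicates for
type-I error (1,000 resamples) and planted-class recovery, 50 random genes
against the exhaustive $2^8$ enumeration, 100 random transcripts for the
diploid round trip, and a few thousand simulated reads for assignment
checks. These sizes give tight Monte-Carlo bands while keeping a full run
in well under a minute on one core.

## A small worked example

```{r example}
cfg <- sim_config(n_genes = 300, n_cell_types = 1, n_stages = 1,
                  class_probs = c(biallelic = 0.6, maternal = 0.1,
                                  paternal = 0.1, strain_B = 0.1,
                                  strain_C = 0.1),
                  mean_log_expression = c(meanlog = log(200), sdlog = 0.5),
                  seed = 42)
sim <- simulate_counts(cfg)
res <- classify_ase(sim$counts, sim$samples,
                    test = test_config(n_resamples = 1000, seed = 42))
res |>
  left_join(select(sim$truth, gene, class), by = "gene") |>
  count(class, category)
```

Every planted family is recovered here because each makes up a fifth of
the tested genes. Shrink a family's share (say 200 strain-biased genes in
2,000) and the discreteness limit discussed above bites: their exact
p-values of $2/256$ no longer clear BH within a condition, and the
gene-level strain screen across conditions becomes the detection route.

## Known limitations

- Diagnostic-site read assignment is exact but ignores multi-mapping;
  on real data an EM-based diploid quantifier distributes such reads
  probabilistically, and the difference is unknowable at toy scale.
- The module works on transcript sequences directly; genome-scale
  annotation liftover is equivalent only for transcript-contained
  variants.
- The atlas reports per-condition calls; transcript-isoform-specific
  imprinting is out of scope.
- BH scope (within condition x orientation) and the both-gates
  classification rule are documented defaults, configurable where the
  underlying design choice is genuinely open.
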