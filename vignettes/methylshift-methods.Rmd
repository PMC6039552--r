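---
title: "Models and design decisions in methylshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design decisions in methylshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylshift)
```

# Scope

methylshift analyses prokaryotic whole-genome bisulfite sequencing (WGBS)
methylomes across a stress/recovery design: it calls 5mC sites from
per-cytosine count tables, detects differentially methylated regions
(DMRs), and quantifies how much of a stress-induced methylation pattern
persists after the stress is removed. The package consumes cytosine-report
style count tables (replicon, 1-based position, strand, methylated count,
unmethylated count, context, trinucleotide); read trimming and bisulfite
alignment are upstream of its scope.

# The site-calling model

In bisulfite sequencing, unmethylated cytosines are chemically converted
and read as T while methylated cytosines remain C. Conversion is
incomplete: a fraction $R$ of unmethylated cytosines fails to convert and
is read as C anyway. $R$ is estimated by pooling every cytosine of an
unmethylated spike-in control (a lambda-phage analogue):
$\hat R = k_{\mathrm{ctrl}} / n_{\mathrm{ctrl}}$, the complement of the
usual "bisulfite conversion rate".

At a genomic cytosine with $n$ reads of which $k$ report methylation, the
null hypothesis "no methylation" makes $k$ binomial with success
probability $R$. The test is one-sided,

$$p = P(X \ge k), \qquad X \sim \mathrm{Binomial}(n, R),$$

because the only alternative of interest is an excess of apparently
methylated reads over the non-conversion noise. p-values are adjusted by
Benjamini–Hochberg, and a site is an mC site when its depth is at least
`min_coverage` (default 5) and its q-value at most `q_max` (default 0.05).

Two decisions here were genuinely open:

* **Testing universe.** BH is applied over sites with depth
  `>= min_coverage` (filter before correction). Applying both filters
  jointly is the conservative, reproducible reading of a joint
  coverage-and-FDR rule; the universe is a function argument, so an
  all-covered-sites analysis is one parameter away.
* **FDR procedure.** "FDR q-value" is interpreted as Benjamini–Hochberg,
  the default meaning in this literature.

Methylation levels are the methylated read fraction corrected for
non-conversion, $\mathrm{ML} = (k/n - R)/(1 - R)$, clamped to $[0,1]$:
at finite coverage the raw value can leave the unit interval (for example
$k=0$ gives a negative numerator), and levels are proportions by
definition.

## Context classification

A cytosine's context is a deterministic function of the two bases
downstream on its own strand: CG if the next base is G, CHG if the base
after that is G, CHH otherwise (H = A, C or T). Cytosines within 2 bp of a
replicon end, or with an N among the two downstream bases, have undefined
context and are excluded from the site universe — a negligible count on
any realistic replicon. Opposite-strand CG cytosines are **not** collapsed
into one site: prokaryotic methylation motifs are strand-asymmetric, and
strand-specific accounting is the only reading consistent with per-site
totals in this design. Site identity across conditions is the
(replicon, 1-based position, strand) triple.

# DMR detection

Fixed 200 bp windows sliding by 40 bp tile each replicon (trailing partial
windows are dropped). Within a window, the methylated and unmethylated
read counts of the two samples are pooled over the cytosines covered at
`min_coverage` in **both** samples, giving a 2×2 table tested with the
two-sided Fisher exact test. Windows with fewer than `min_sites` (default
5) shared covered cytosines are not tested. BH correction runs across all
tested windows genome-wide; a window is significant when `q <= q_max`
**and** the pooled level difference exceeds `min_diff` (default 0.1) in
absolute value. Significant windows of the same direction that overlap or
are book-ended merge into DMRs; opposite directions never merge.
Hyper/hypo is the sign of (sample B − sample A) pooled level, i.e.
relative to the comparison (stressed) sample.

Two reconstruction choices deserve note:

* **Read pooling, not site counting.** The 2×2 table pools read counts per
  window, the Fisher mode of the sliding-window DMR tools this module
  mirrors.
* **Effect-size guard after, not before, correction.** `min_diff` is a
  significance condition applied alongside the q-value threshold, not a
  pre-test eligibility filter. Filtering the tested set on an observed
  effect size would bias the BH correction and break the null calibration
  property the test suite checks (on two samples drawn from one methylome,
  the significant-window fraction stays near `q_max`).

A practical consequence of read pooling in sparse bacterial methylomes:
when a count table contains every genomic cytosine, window-level pooled
differences are diluted by the unmethylated majority and rarely reach
`min_diff`; regional signal must either be dense or `min_diff` lowered.
Genes are DMR-related when their gene body overlaps a DMR by at least
1 bp.

# Multi-condition comparison

The three per-condition mC-site sets (baseline, stressed, recovered) are
decomposed into the seven disjoint Venn cells. Writing the cells as
A-only, …, ABC:

* sites **lost** under stress: A-only + AC-only;
* sites **gained** under stress: B-only + BC-only;
* **preserved** fraction: BC-only / gained — stress-induced sites still
  present after recovery;
* **regained** fraction: AC-only / lost — lost sites that returned.

Fractions with zero denominators are reported as NA. The same machinery
applies to gene-level sets (a gene is methylated when at least one mC site
overlaps its body).

Per-context "proportion methylated" uses, by default, the cytosines
covered at `min_coverage` in that sample as denominator ("covered" mode),
which is robust to coverage differences between samples; a "genomic" mode
(all context-defined cytosines) is available, and the two coincide at full
coverage. Level summaries are five-number summaries of corrected levels
over mC sites using linear interpolation between order statistics
(`quantile(type = 7)`), fixed so that exact tests are possible.
TE-type sites are mC sites *exclusively* within a transposable element —
overlapping a TE interval and no gene body. Functional-region assignment
uses the precedence gene body > upstream > downstream > intergenic with
100 bp flanks by default; the precedence is a deterministic convention for
overlapping annotations, and ties within a tier go to the first annotated
gene.

# Enrichment and physiology utilities

Pathway over-representation of DMR-related genes is the upper-tail
hypergeometric test with BH correction; the default universe is all genes
of the supplied mapping, pathways with fewer than 2 genes or zero overlap
are skipped before correction. The physiology helpers implement the
specific growth rate $\mu = (\ln OD_2 - \ln OD_1)/(t_2 - t_1)$ from
endpoint readings (the formula is explicit; no curve fitting), relative
qPCR expression by $2^{-\Delta\Delta C_T}$, and a growth-rate comparison
using per-replicate endpoint rates and Welch's two-sample t-test — the
unequal-variance default, since nothing justifies assuming equal
variances; with degenerate zero-variance input the p-value is 1 for equal
means and NA otherwise.

# The synthetic generator

The generator emulates the study conditions the pipeline targets:

* **Prevalences** default to 3.05% CG, 0.90% CHG, 1.03% CHH — the
  unstressed per-context methylated proportions the pipeline is built
  around.
* **Levels** of methylated sites draw from Beta(2, 5) per context. The
  shape is a modelling choice (only box-plot summaries exist to emulate);
  it keeps most levels well above the detection floor at the ~163× median
  depth of the emulated study while retaining realistic spread.
* **Stress shift** defaults: 41% of methylated sites lose methylation;
  surviving sites gain `level_delta = 0.10` (additive, clipped at 1 —
  additive was chosen over multiplicative as the simplest "level increase
  at surviving sites" model); 0.17% of unmethylated sites gain
  methylation, which at the default prevalences makes the gained set about
  12% of the baseline methylated set; after recovery 45.3% of gained sites
  are preserved and 0.78% of lost sites regained, at their original
  levels. Every set is recorded exactly in a truth ledger whose
  conservation identities (|methylated| = |lost| + |survived|, recovered
  = survived + preserved + regained) are asserted in tests.
* **Counts** follow the protection model: observed methylation probability
  $m + (1-m)R$, with depth from a Poisson (default mean 50, a desk-scale
  choice), negative binomial, or fixed model — fixed depth exists for
  exact-depth calibration checks. This is precisely the model the level
  correction inverts, so simulator and estimator are mutually consistent.
  A conversion control is generated alongside from a fully unmethylated
  20 kb genome.
* **Seeding**: one master seed derives fixed per-stage streams, so every
  stage is individually reproducible and outputs are byte-identical under
  a fixed seed.

What the generator does **not** emulate: read-level artefacts (sequencing
error, mapping bias, PCR duplicates), overdispersion of methylation counts
beyond the binomial, strand-biased motifs, and partial bisulfite
resistance of m4C. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness to
alignment artefacts in real libraries.

# Problem sizes and numerical conventions

The test suite and the reproduction script use 20–200 kb genomes
(~10,000–95,000 cytosine sites), chosen as the package's working scale for
its fully-simulated analyses. Exact-test implementations are checked
against independent enumeration oracles (binomial tails for all n ≤ 50,
Fisher two-sided p for all 2×2 tables with N ≤ 40, hypergeometric tails
for N ≤ 30) at absolute tolerance 10⁻⁹ or tighter. Fisher's two-sided
p-value follows the standard convention (sum of table probabilities not
exceeding the observed table's, with a 10⁻⁷ relative tolerance); a 2×2
table with an all-zero margin returns p = 1. Ties in p-values need no
special handling under BH. Degenerate inputs are errors where a contract
is violated (empty control table, zero coverage in the level formula,
non-C base in context classification) and conventions where a convention
is safer (empty Venn denominators → NA).

# Known limitations

* The binomial test ignores overdispersion between molecules; a
  beta-binomial extension would be needed for heavily overdispersed
  libraries.
* DMR detection has no smoothing or HMM segmentation; it reconstructs a
  sliding-window Fisher approach, and its merging rules, while
  deterministic, are a documented reconstruction rather than a published
  algorithm.
* Enrichment is a generic hypergeometric test on a user-supplied mapping;
  it does not reproduce any specific annotation database's gene-set
  curation.
* The pipeline's third condition is optional but the retention statistics
  require all three.
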