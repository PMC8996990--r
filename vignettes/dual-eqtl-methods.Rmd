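---
title: "Dual-mode eQTL mapping and somatic segment analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-mode eQTL mapping and somatic segment analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualqtl)
```

## The analysis in one paragraph

dualqtl implements an integrated regulatory analysis for paired tumor/normal
cohorts, built around one idea: a cis-eQTL can be scanned in two complementary
modes. The *classical* mode correlates minor-allele dosage with the log2
expression signal in normal tissue; the *modified* mode correlates the same
dosage with the per-case tumor-vs-normal log2 fold change. Because the fold
change subtracts the normal signal, a variant that raises (or lowers)
baseline expression without a matching tumor effect produces correlations of
*opposite sign* in the two modes — the direction-flip phenomenon the
intersection stage classifies. Around this core sit a pathway-window SNP
selection stage with a case-control screen, a gene-level somatic
copy-number / allelic-imbalance / LOH caller for paired SNP-array signals,
and downstream characterization (paired differential expression with BH FDR,
median-split Kaplan–Meier log-rank survival).

## Statistical model and assumptions

**Spearman test.** For a SNP–probe pair, let $g_i \in \{0,1,2\}$ be dosages
and $y_i$ the phenotype (normal-layer signal, or fold change
$t_i - n_i$ on the log2 scale). We compute $\rho$ as the Pearson correlation
of average ranks (mean ranks on ties) over pairwise-complete observations,
and the two-sided p-value from

$$t = \rho\,\sqrt{\frac{n-2}{1-\rho^2}} \sim t_{n-2},$$

with $p = 0$ by convention when $|\rho| = 1$. The t approximation, rather
than the exact permutation null, is the deliberate choice: at the cohort
sizes this analysis targets ($n \approx 100$) the two are practically
indistinguishable, and the approximation is the formula under which the
package's reference p-values reproduce. Its small-sample error is real and
quantifiable: enumerating all $n!$ rank permutations shows a worst-case
absolute deviation of 0.077 at $n=5$, 0.048 at $n=6$, 0.027 at $n=7$ and
0.024 at $n=8$ for tie-free data (larger when the dosage vector is heavily
tied). The test suite asserts the implementation stays inside these
enumerated bounds; users testing at $n < 10$ who need exact inference should
treat reported p-values as approximate. Tests with fewer than 3 complete
pairs or a constant vector are skipped with a recorded reason, never
silently dropped.

**Why log2 differences for "fold change".** Spearman's $\rho$ is invariant
under strictly monotone transforms of the phenotype, and
$\log_2(T/N) = t - n$ is a monotone function of the linear ratio $T/N$, so
computing the modified-mode phenotype as the difference of log2 signals is
equivalent to any monotone fold-change convention while staying symmetric
around 0.

**Association screen.** Case status is regressed on additive dosage plus
age (continuous, years) and gender (binary indicator) with a logistic GLM;
the per-allele odds ratio carries a Wald 95% CI. A SNP is screen-significant
iff $p < \alpha$ *and* the CI excludes 1. Under the Wald construction the two
conditions coincide; both are evaluated and any disagreement (which would
signal a non-Wald interval) is surfaced in the output. Dosage coding is
additive because that is the standard GWAS treatment of an ordinal genotype;
logistic is the natural link for a binary disease outcome. Constant-dosage
SNPs and separated fits are skipped with reasons.

**Window mapping.** Gene bodies are 0-based half-open (BED); a SNP at
1-based position $P$ maps to a gene iff
$\mathrm{start} - w \le P - 1 < \mathrm{end} + w$ with $w$ = 20 kb by
default. Windows are symmetric and strand is ignored — a symmetric window is
the same interval regardless of orientation. Mapping is monotone in $w$:
enlarging the window can only add links.

**Multiple testing.** The scan reports the Bonferroni threshold
$\alpha/m$ exactly, where $m$ counts every attempted test; nominal
significance is strict $p < \alpha$. Downstream differential expression uses
Benjamini–Hochberg adjustment (`stats::p.adjust`).

**Intersection and direction classes.** A shared pair is significant in
both modes; its direction is `flip_neg_to_pos` (classical $\rho < 0$,
modified $\rho > 0$), `flip_pos_to_neg`, or `concordant`. A $\rho$ of
exactly 0 — possible only through degenerate ties — is classed concordant;
the tie-break is recorded here because it can never matter away from exact
zeros. Shared *genes* split into those carried by identical (SNP, probe)
pairs and those significant in both modes only through different
SNPs/probes; the two sets are disjoint by construction.

## Somatic segment calling

The paired-array stage works at the gene level because the analysis unit is
the gene: per-SNP thresholding followed by window aggregation, not
segmentation. This is a transparent, configurable rule — circular binary
segmentation and purity/ploidy modelling are out of scope.

Per SNP: copy-number state from tumor logR (`gain` above +0.2, `loss` below
−0.2, else neutral). At germline-heterozygous SNPs only: LOH when tumor BAF
reaches a homozygous value (≥ 0.85 or ≤ 0.15) with logR ≤ 0, and allelic
imbalance when $|BAF - 0.5| > 0.2$ without LOH. Requiring non-positive logR
for LOH separates deletion/copy-neutral LOH from gain-driven BAF splits
(a duplicated allele pushes BAF to 2/3, not to 1). Homozygous germline SNPs
are uninformative for both allelic flags.

Per gene and case, over the window SNPs: `gain` if ≥ 50% of CN-informative
SNPs are gain; else `loss_or_loh` if ≥ 50% are loss or any het SNP is
LOH-flagged; else `ai_only` if any het SNP is AI-flagged; else `none`. The
precedence gain > loss_or_loh > ai_only makes the four categories mutually
exclusive so cohort frequencies partition the cohort: for every gene,
`freq_total = freq_ai_only + freq_gain + freq_loss_loh` holds on unrounded
values. Raising a CN threshold can only remove calls (monotonicity, tested).
A gene whose window contains no informative SNP is `none`; allelic states
are genuinely unobservable there.

Expression abnormality per gene and case thresholds the probe-averaged log2
fold change at ±1 (two-fold); `freq_abnormal = freq_over + freq_under`.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without any
external download. Its defaults encode the cohort structure the analysis
targets, chosen once: a genotyping cohort of 1423 cases / 1660 controls, a
paired-expression subset of 100 cases, an array subset of 76 cases, ±20 kb
windows, ages uniform on 39–71, 60% male, baseline median survival 23.3
months, additive Gaussian noise of 0.5 on the log2 scale, and per-gene
somatic rates (gain 0.10, loss 0.07, LOH 0.05, AI 0.22) that put the total
alteration frequency near the middle of the range such cohorts show. All
randomness flows from one master seed through fixed per-component
sub-streams, so identical configurations are bit-reproducible.

What it emulates, and how:

* **Genotypes**: per-SNP MAF uniform on a configurable range; controls drawn
  under Hardy–Weinberg; cases drawn from the retrospective distribution
  $P(G = g \mid \mathrm{case}) \propto \mathrm{HWE}(g)\,e^{bg}$, so a
  planted per-allele log odds $b$ is recovered by the allelic odds ratio.
  SNPs are placed so every gene window holds at least one (mid-gene anchor);
  the rest are uniform. SNPs are independent — no linkage disequilibrium.
* **Expression**: normal layer = per-probe baseline + $\beta_N \cdot g$ +
  noise; tumor layer = baseline + shift + $\beta_T \cdot g$ + independent
  noise. Planted effects route to the probes of the gene(s) whose window
  contains the SNP. Setting $\beta_N \neq 0,\ \beta_T = 0$ plants the
  direction-flip mechanism by construction, since
  $\mathrm{cov}(g,\, t-n) = -\beta_N \mathrm{var}(g)$.
* **Somatic signals**: per gene and case a latent state
  (gain/loss/LOH/AI/none); window SNPs get logR and BAF consistent with it
  (gain: logR +0.5 with BAF 1/3 or 2/3; loss: logR −0.5 with het BAF 0/1;
  copy-neutral LOH: logR 0 with het BAF 0/1; AI: logR 0 with het BAF
  0.25/0.75). With noise at 0 the caller recovers the latent states exactly
  on gene-cases with at least one het window SNP.
* **Survival**: exponential event times with log-hazard linear in one
  probe's centered normal-layer expression; independent uniform
  right-censoring at a configurable probability.

What it does **not** emulate — and hence what green tests do not establish
about real data: probe-level intensity artifacts and normalization error,
LD between SNPs, population stratification, segment-level (multi-gene)
somatic events, tumor purity and subclonality, and informative censoring.
Passing tests demonstrate the pipeline's statistical machinery is correct
under the stated generative model, not that biological conclusions transfer.

## Numerical and degenerate-input choices

* Spearman p-values: t approximation (above); $p = 0$ at $|\rho| = 1$.
* Missing genotypes: pairwise-complete per test, with `n_used` reported per
  result; planted expression effects treat a missing dosage as 0 effect.
* Identical tumor and normal layers make the fold-change phenotype constant:
  every modified-mode test is skipped with a reason rather than erroring.
* In the paired DEG test, a probe with all-zero differences reports
  $t = 0, p = 1$; nonzero constant differences are skipped.
* Median splits send ties to the low group; a split needing a group of
  fewer than 2 cases is an error.
* An empty screen result propagates as an empty test set with warnings; the
  pipeline still completes and writes (empty) stage tables.
* Wald CIs use $\pm 1.96\,\mathrm{SE}$ on the log-odds scale; fits with
  SE > 10 or $|\hat\beta| > 15$ are treated as separated and skipped.

## Problem sizes used by the test suite

The suite exercises the full stack at deliberately modest sizes: HWE checks
at 40 000 draws; odds-ratio recovery at 5 000/5 000; type-I error over 1000
null cis pairs at $n = 100$; direction-flip recovery over 200 replicates at
$n = 100$, $\beta_N = -0.5$, noise 0.5; somatic round-trips over 76-case
cohorts with 40 SNPs per gene window; CI coverage over 100 replicates at
2000/2000. These sizes give Monte-Carlo error comfortably inside the asserted
bounds while keeping a full run in the tens of seconds.

## Known limitations

* The eQTL engine is rank-based and covariate-free; covariate-adjusted or
  latent-factor eQTL models (PEER and kin) are out of scope, as are
  trans-eQTLs — only window-mapped cis pairs are tested.
* The somatic caller does not estimate integer copy number and is blind to
  events whose footprint does not reach the gene window.
* The survival stage is the two-group log-rank test only; no Cox or
  multivariable modelling.
* The generator draws SNPs independently; analyses sensitive to LD structure
  cannot be validated against it.
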