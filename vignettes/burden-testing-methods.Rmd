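---
title: "Monte-Carlo burden testing from population summary statistics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte-Carlo burden testing from population summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burdenMC)
```

## The model

A rare-variant burden test aggregates qualifying variants within a unit — a
gene, a protein domain, a pathway — into a single count and asks whether the
case cohort carries more of them than expected. When no control genotypes
exist, the expectation must come from population summary statistics. For an
ancestry group of $N$ individuals and a variant with $AC$ alternate alleles
among $AN$ called alleles in the reference database, the alternate-allele
count contributed by a randomly drawn control cohort is exactly

$$X_v \sim \mathrm{Hypergeometric}(AN,\; AC,\; 2N),$$

i.e. $2N$ alleles drawn without replacement from the finite pool of $AN$
alleles. Sampling alleles (rather than individuals) is a deliberate
convention: homozygotes then arise naturally in simulation (two alternate
alleles landing in one individual's two slots), and the observed cohort
burden — the summed alternate-allele dosage, homozygotes counting 2 — lives
on exactly the same scale. The unit burden is $X = \sum_v X_v$ with variants
treated as independent; the LD-pruning step exists precisely to license that
assumption.

The null distribution of $X$ is estimated by Monte Carlo (default $10^6$
iterations; the desk-scale profile uses $10^5$) and the empirical p-value is

$$p = \Pr(X \ge B) \approx \frac{\#\{X_i \ge B\} + 1}{n + 1},$$

the add-one estimator, which can never return 0; results beyond the
simulation floor are displayed as `< 1/iterations`. Per-ancestry tests are
combined by summing simulated burdens per iteration index across ancestries
(the joint null) and comparing with the summed observed burden. An exact
oracle — discrete convolution of the per-variant hypergeometric PMFs —
is provided for small configurations and anchors the engine's test suite;
the Monte-Carlo path and the convolution path never share code.

### Why a combined p rather than meta-analysis

The joint per-iteration sum is the exact null of the pooled statistic
$\sum_{pop} B_{pop}$ under independence of ancestry groups, requires no
distributional approximation, and costs nothing extra because the
per-iteration totals are already in memory. Per-ancestry streams are summed
by shared iteration index; since the streams are mutually independent, the
pairing is arbitrary and any index alignment yields the same distribution.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `iterations` | 1e6 (1e5 at desk scale) | Monte-Carlo control cohorts per unit and ancestry |
| `af_max` | 0.01 | qualifying AF ceiling, enforced in *every* ancestry |
| `cadd_min` | 20 (0 for domains) | Phred-scaled CADD floor (~top 1% deleterious) |
| `min_group_size` | 10 | smallest ancestry group tested; smaller groups become UNKNOWN |
| `exome_wide_alpha` | 2.5e-6 | significance threshold annotated on results |
| DUST threshold / window | 28 / 64 | symmetric-DUST score (x10 scaling) and max interval length |
| homopolymer min / pad | 7 bp / 10 bp | run length; mask extension on both sides |
| `sor_max`, `excesshet_max` | 3, 100 | strand-bias and heterozygote-excess site filters |
| `hwe_p_min`, `missing_max` | 1e-3, 0.01 | exact-HWE and missingness filters |
| LD `window`, `r2_min` | 10 kb, 0.95 | pair distance bound; `>=` in the database round, `>` in the cohort round |
| `prob_threshold` | 0.9 | minimum winning-class probability for ancestry assignment |
| MTR `window` | 31 codons | sliding window, edge-truncated |

Filter hardness is fixed by design: `db_qc_fail`, `gnomadDP0`, `ns5000`,
`lcr`, `sor`, `missing` and `AC0` exclude; `hwe`, `excesshet` and the LD
flags annotate. HWE and heterozygote-excess metrics are most informative in
larger cohorts, so they are kept non-penalizing; the others describe defects
that bias the case/control comparison itself.

## Numerical and convention choices

**Variant keys.** Variants are indexed by a reversible 64-bit packing
(5 bits chromosome, 28 bits position, 31-bit allele block; alleles totalling
more than 11 bases fall back to a hash bucket with a marker bit). Base R has
no unsigned 64-bit integer and signed containers would misorder chromosome
codes $\ge 16$, so the packed value is surfaced as a 16-character hex string
whose lexicographic order equals unsigned numeric order.

**DUST convention.** The interval score is
$10 \sum_t c_t(c_t-1)/2 \,/\, (L-3)$ over triplet counts; "perfect"
intervals (no proper subinterval scoring strictly higher, length at most the
window) are reported merged. The x10 scaling makes the published threshold
28 integral; the window length (64) is not stated alongside the threshold in
the method we follow and is fixed here as a documented, configurable
default.

**HWE exact test.** Two-sided: the summed probability of all heterozygote
configurations (conditioned on allele counts) no more likely than the
observed one, with a $1+10^{-9}$ tie tolerance. Heterozygote excess is the
one-sided upper tail, Phred-scaled, used when `ExcessHet` is absent from a
VCF.

**AC0.** A carrier *passes* when its het-call allele balance lies in
[0.2, 0.8] and it is not simultaneously low-depth (<10) and low-quality
(<20); the flag fires when no carrier passes. The prose this rule derives
from is ambiguous; this reading matches its stated intent (the only
unskewed genotypes are the unconfident ones). Homozygous-alt carriers have
no defined het balance and are judged on depth/quality alone; carriers
lacking AD are not failed on balance. Indel allele balance uses the
alt-supporting read fraction regardless of allele length.

**CADD at domain level.** Domain-level testing applies no CADD filter.
We read "CADD > 0" as *no requirement at all* (variants without a score
included): the worked-example variant table includes an unscored variant
under that rule, which settles the ambiguity in favor of inclusiveness.

**LD tie-breaks.** Within a linked pair the better-called variant (larger
`AN`, or more non-missing genotypes in the cohort round) is retained, ties
breaking toward the smaller packed key; pruning is greedy by linkage degree,
so a fully linked clique of size $k$ loses exactly $k-1$ members. Database
pruning is ancestry-selective: a flagged variant is removed only from that
ancestry's simulation inputs, never from the table itself.

**Effect sizes.** Collapsed scores are 0 (no qualifying variant), 1 (only
heterozygous), 2 (any homozygous); missing genotypes count as non-carrier.
Logistic regression of status on score gives $OR = e^\beta$ with Wald CIs
and provably reduces to the 2x2 cross-product OR for binary scores (tested
to 1e-6); separation falls back to Firth's bias-reduced fit. Control scores
are simulated from the same hypergeometric engine; the "conservative"
summary is pinned to the iteration-wise upper quartile of carrier counts
(configurable to the mean) so control carriage errs high and the estimated
OR errs low.

**Power.** The power operation models allele counts binomially (a
large-population approximation consistent with a 100,000-individual control
pool) and tests each replicate with a two-sided Fisher exact test on the
allele 2x2 table. A printed requirement of ~1,380 cases for OR 2.5 at
AF 26% under these assumptions is not recoverable from any standard
allele-count test we examined; the operation is generic and reports what the
stated assumptions actually imply rather than forcing that figure.

**Replication permutation test.** The statistic is the total qualifying
allele count in cases; the null permutes case/control labels over pooled
individuals. The externally reported p for the replication analysis this
mirrors is not recoverable under naive label permutation (the original
design was plausibly ancestry-stratified but is unstated), so no test pins
that value.

## What the synthetic generator emulates — and what it does not

`simulation_config()` states the world once: four ancestry groups of 40
samples (a diverse ~160-sample cohort), 2,000 genes x 8 variants,
allele frequencies log-uniform on $[10^{-5}, 5\times10^{-3}]$ (all rare),
half of variants with CADD $\ge 20$, gnomAD-v2-exome-like allele numbers per
ancestry, 0.1% missing genotypes, 2% low-quality genotypes, mild
allele-balance noise. Null cohorts are drawn *exactly* under the engine's
own sampling law (hypergeometric allele counts placed uniformly into allele
slots), so calibration tests probe the inference machinery, not model
mismatch. Spiked genes instead draw per-individual genotypes at an
OR-inflated carrier frequency, with the truth manifest recording gene,
target OR and carriers.

The generator does **not** emulate: realistic LD structure (only planted
duplicate columns for pruning tests), sequencing reads, relatedness,
batch effects, population substructure within ancestries, or annotation
error. A green calibration test therefore establishes that the engine is
correct *given* its independence and sampling assumptions — not that those
assumptions hold in any particular real dataset.

## Calibration diagnostics and discreteness

The reported p-value $\Pr(X \ge B)$ of a discrete statistic is
*superuniform*: $\Pr(p \le s_k) = s_k$ holds exactly only at the support
points $s_k$ of each unit's burden distribution, and between them the CDF
sits below the diagonal. Pooled over 2,000 genes with low expected burdens,
a plain KS test against the uniform would reject for discreteness alone,
telling us nothing about correctness. The calibration suite therefore tests
the randomized probability integral transform

$$u = \frac{\#\{X > B\} + U\,(\#\{X = B\} + 1)}{n + 1}, \qquad U \sim \mathrm{Unif}(0,1),$$

which is uniform under the null for a discrete statistic, while separately
asserting the *conservative* behaviour of the reported p-values (empirical
tail fractions never exceeding nominal levels, zero exome-wide hits on null
cohorts). Burden results carry `n_gt` and `n_eq` columns so the diagnostic
needs no access to raw simulation draws.

## Degenerate inputs and edge policies

* `AC = 0` variants simulate as point mass at 0; `AN < 2N` is an error
  (population smaller than the simulated cohort).
* `B = 0` gives $p = 1$ exactly; empty aggregation units are errors, while
  domains with no mappable variants are reported as `NA` rows.
* Monomorphic sites have undefined genotype correlation and are skipped by
  cohort LD pruning; monomorphic margins return $r^2 = 0$ by convention.
* Multiallelic VCF records are refused with normalization advice rather than
  guessed at, because AC/AN semantics are per alternate allele.
* Missing FORMAT fields yield absent metrics, never silent zeros.
* MTR windows with no observed variants are `NA`, not 0; edge windows are
  truncated, not dropped; in-frame stop codons (other than a terminal stop)
  are errors.

## Known limitations

* Variant independence after pruning is an approximation; residual LD below
  the 0.95 threshold inflates simulated burden variance slightly, which is
  conservative for enrichment detection.
* The ancestry classifier is a compact bagged-CART forest built in-package
  (no random-forest library is available in the target environment); it
  matches the contract (per-class probabilities, OOB accuracy, determinism
  under seed) but is not tuned for adversarial admixture.
* Cohort LD pruning is quadratic within windows and the DUST implementation
  is $O(nw^2)$ worst-case: both are sized for exome targets and fixtures,
  not whole-genome scans.
* p-values are bounded below by the iteration count; exome-wide claims at
  $2.5\times10^{-6}$ require the full $10^6$ iterations.
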