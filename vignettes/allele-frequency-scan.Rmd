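---
title: "Scanning tiny cohorts for allele-frequency differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning tiny cohorts for allele-frequency differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqscan)
```

## The problem

Exome sequencing of a handful of individuals — seven, say, giving 14
autosomal alleles — is enough to take a first census of the potentially
deleterious coding variation segregating in an understudied population,
and to ask which of those alleles sit at a frequency clearly different
from the large continental reference panels. freqscan implements that
analysis as a reusable pipeline: variant triage by functional impact and
health-database linkage, a combined binomial + Fst + q-value
differentiation scan against per-continent panel frequencies, and a
subsampling study of how representative such a tiny cohort's allele
frequencies are of the population it was drawn from. A Balding–Nichols
simulator generates structured-population data with known truth so every
stage can be validated without any external download.

## The statistical model

### Cohort allele statistics

Genotypes are diploid calls at biallelic autosomal SNPs, stored as
alternate-allele dosages 0/1/2 with an explicit missing state. Failed
genotypes are accounted for in the allele frequency: at a site with $c$
successfully genotyped individuals and $x$ alternate alleles among them,
the frequency is $x / 2c$, and a site with no called genotypes carries an
undefined frequency (`NaN`), which is deliberately distinct from a
frequency of zero. Half-called diploid genotypes (e.g. `0/.`) are treated
as fully missing because every downstream count is in whole alleles.

### The differentiation scan

For each site and each continental panel with data, the cohort's count
$x$ out of $n$ alleles is tested against the panel frequency $p$ under
the null $X \sim \mathrm{Binomial}(n, p)$. Two separate one-tailed exact
tests are run: $P(X \ge x)$ for enrichment above the panel and
$P(X \le x)$ for depletion, with the observed count included in the tail
(a switch gives exclusive tails). The panel frequency enters as a fixed,
known parameter — no uncertainty propagation — because sampling noise in
the panel estimate is handled by the second statistic:

The two-population Weir–Cockerham $\theta$ is computed from the cohort
and panel allele counts on the haploid-allele (ANOVA) parameterisation:
with among- and within-population mean squares

$$\mathrm{MSP} = n_1(p_1-\bar p)^2 + n_2(p_2-\bar p)^2, \qquad
  \mathrm{MSG} = \frac{n_1 p_1 q_1 + n_2 p_2 q_2}{n_1+n_2-2},$$

and $n_c = (n_1+n_2) - (n_1^2+n_2^2)/(n_1+n_2)$,

$$\hat\theta = \frac{\mathrm{MSP}-\mathrm{MSG}}
                    {\mathrm{MSP} + (n_c-1)\,\mathrm{MSG}}.$$

The raw estimate can be negative; a zero-floored copy is used for
thresholding only, and the 0/0 case (both samples monomorphic for the
same allele) is returned as 0 with an explicit flag. A Hudson-style
estimator is provided purely as a cross-check.

Multiple testing is controlled with Storey q-values,
$q_{(j)} = \min_{k \ge j} \pi_0\, m\, p_{(k)} / k$. The default
$\pi_0 = 1$ makes the q-values exactly the Benjamini–Hochberg adjusted
p-values; a smoother mode estimates $\pi_0$ on a $\lambda$ grid with a
natural cubic smoothing spline evaluated at the largest $\lambda$,
capped into $(0, 1]$. Families are formed per continent and — by
default — per direction, since the two one-tailed tests are separate
hypotheses; a pooled-direction family is available as a switch.

A site is called *enriched* against a continent when both conditions
hold with strict inequalities: $\hat\theta > 0.25$ and $q < 0.05$. The
Fst cutoff guards against panel-frequency sampling noise; the exact
binomial tail is robust to the tiny cohort count. Degenerate panel
frequencies (0 or 1) are tested exactly, so p-values of 0 are legal and
propagate through the q-value step.

### Variant triage

Each site's functional category is the most severe across its
transcripts under the fixed order nonsense > splice > missense >
silent > noncoding (the severity order is our choice; one category per
site is required and no standard total order is mandated elsewhere). A
missense variant is *potentially deleterious* when either predictor
fires: SIFT "deleterious", or PolyPhen "probably damaging" or "possibly
damaging" — the liberal union, wider than consensus scores. The flag is
restricted to missense by default; `include_splice = TRUE` extends
eligibility to splice variants for sensitivity analyses. Health linkage
is assigned in three tiers: tier 3 when the specific SNP is already
known (rsID match, or gene + amino-acid substitution match for records
without an rsID; matching is case-insensitive), tier 2 when only the
gene is linked, tier 1 otherwise; tier 3 takes precedence. Summaries
count deleterious variants at allele-count cutoffs (defaults ≥1 and ≥6
of the cohort's alleles) split by tier, with percentages displayed
half-up to whole percent while full-precision shares are retained.

### Representativeness

Paired frequencies from a small and a large sample are compared with the
Pearson product-moment correlation; the 95% interval is the Fisher
transform $\tanh(\operatorname{atanh} r \pm 1.96/\sqrt{n-3})$ (the
quantile is fixed at 1.96 to match convention) and the p-value is the
two-sided $t$ test with $n-2$ degrees of freedom, alongside an ordinary
least-squares fit. The subsampling study repeatedly draws $k$
individuals (optionally as a fixed mixture across populations, e.g.
3 + 2 + 2 from three panels) and a disjoint large sample of $m$, and
correlates their per-site frequencies; the large sample excludes the
small sample's individuals because overlap inflates the correlation (a
switch permits overlap for the self-comparison sanity check, which must
give exactly $r = 1$). Sites monomorphic in both samples of a replicate
are dropped from that replicate — they carry no information about
frequency agreement. Replicate seeds are derived from the master seed by
a counter and recorded in the output.

## The synthetic-data generator

The generator emulates the study design it is meant to test: four
continental panels of 379/296/185/242 individuals and a cohort of seven
split 3/2/2 across three ancestry subgroups, each subgroup drawing from
one continental panel's frequencies. Per site, an ancestral frequency
$p_0$ is uniform on $[0.05, 0.95]$ (bounds avoid degenerate Beta
parameters); each population's frequency is Balding–Nichols,
$\mathrm{Beta}\!\left(p_0\frac{1-F}{F},\,(1-p_0)\frac{1-F}{F}\right)$,
whose variance is $F p_0 (1-p_0)$, so the pairwise Weir–Cockerham
$\theta$ between two populations simulated at divergence $F$ recovers
$F$ — the parameter-recovery test the suite runs at
$F \in \{0.01, 0.05, 0.1, 0.25\}$. Defaults chosen once: $F = 0.10$ per
panel (typical continental-scale human differentiation), missing-call
rate 0.02, functional-category mix noncoding 0.45 / silent 0.22 /
missense 0.30 / splice 0.02 / nonsense 0.01, deleterious fraction of
missense 0.52, and health-tier proportions 0.72/0.24/0.04.

Spiked "enriched" sites displace the cohort-source frequency away from
the across-panel mean by a configured amount, clipped to
$[0.02, 0.98]$. Site selection prefers sites where the full displacement
fits inside those bounds, so the spiked truth actually realises the
requested effect size; clipped targets are a fallback (with a warning)
when too few such sites exist. With displacement 0 the operation only
labels sites. The annotation/health-database generator makes its tier
labels true by construction — tier-3 sites get an rsID record or a
gene + substitution record (half each), tier-2 sites a gene record only,
and every site gets its own synthetic gene symbol so gene-level linkage
never leaks across sites.

What the generator does *not* emulate: linkage disequilibrium, a
realistic site-frequency spectrum (frequencies are uniform-ancestral,
not skewed toward rare variants), consanguinity and runs of
homozygosity, genotyping error, or admixture *within* an individual
(subgroups are drawn from single source populations). Passing tests
therefore demonstrate the statistical machinery's correctness and
calibration under clean structure, not performance on the full
messiness of real exomes.

## Calibration and power, as the suite measures them

On null data — the cohort drawn from the panel's own frequencies, 10,000
sites, 20 replicates — the fraction of sites called enriched at the
combined thresholds stays below $0.05$ plus three Monte-Carlo standard
errors (empirically it is orders of magnitude below: the combined
Fst-and-FDR requirement is very conservative for $n = 14$). Power on
spiked sites is monotone in the displacement and clears one half at
displacement $+0.5$ with the default panel sizes, while the empirical
false discovery proportion among calls stays within its bound. The
subsampling correlation rises monotonically to 1 as $k$ grows to the
population size. These are the problem sizes the test suite and the
acceptance script use; they were chosen to estimate each rate with
useful precision at interactive runtimes.

## Numerical and design notes

* All frequencies and shares are kept at full precision; display
  formatting rounds half away from zero (two decimals for frequencies,
  whole percent for shares), matching how published tables round.
* Strict inequalities at both scan thresholds; boundary values
  ($\theta = 0.25$ or $q = 0.05$ exactly) are not called.
* If both directions of a test somehow pass (possible only with
  degenerate nulls), the higher direction wins, with a warning.
* Sites absent from every panel form a separate "novel" stratum,
  reported but never tested — a panel frequency of `NA` is an absence,
  never a zero.
* Multi-allelic VCF records are rejected by default (with a count) or
  split into biallelic records on request; indels and non-autosomal
  records are always dropped with counts.
* The pipeline writes tab-separated outputs with a metadata header line
  (tool version, config hash, seed) and a JSON manifest; a re-run with
  the same config is byte-identical, and a final consistency check
  re-derives every summary count from the per-site table.

## Known limitations

The scan treats panel frequencies as fixed and the cohort's alleles as
independent draws, so cryptic relatedness or within-cohort structure
(real small cohorts have both) makes the binomial null optimistic; the
Fst cutoff absorbs some but not all of that. The q-value machinery
assumes the per-site tests are exchangeable within a family, which
ignores linkage between nearby exonic sites. And with 14 alleles the
achievable p-values are coarse: the scan has essentially no power for
panel frequencies near 0.5 unless the cohort is nearly fixed, which is
the intended behaviour of a screen designed to flag only strong
differentiation.
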