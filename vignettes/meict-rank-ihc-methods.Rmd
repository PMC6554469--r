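---
title: "Methods: rank-fraction differential expression and semi-quantitative IHC scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-fraction differential expression and semi-quantitative IHC scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meictools)
```

# The problem

Meiosis-specific cancer/testis (meiCT) genes — `STRA8`, `STAG3`, `SGO2`,
`SYCP3`, `DMC1` — are normally restricted to germ cells; their ectopic
activation in cutaneous T-cell lymphoma (CTCL), and particularly in its
leukemic variant Sézary Syndrome (SS), is a candidate tumour marker. Two
measurement settings raise two distinct statistical problems, and this
package implements both:

1. **Cross-cohort RNA-Seq comparison.** Public SS expression cohorts are
   processed by different labs and pipelines, so their TPM
   (transcripts-per-million) values sit on different global scales and
   cannot be pooled directly. The device used here is a within-sample,
   rank-based normalization that is invariant to any per-cohort monotone
   rescaling, followed by a pooled-null bootstrap test on group means and a
   Bonferroni correction over the gene panel.
2. **Semi-quantitative immunohistochemistry (IHC).** Stained biopsy
   sections are scored by percentage-positivity category and staining
   intensity; the product defines an expression score banded into
   negative / weak–moderate / strong. Band membership across disease
   stages is compared with an exact test on small r×c contingency tables.

# Rank-fraction normalization

For gene $g$ in sample $s$ of an $n$-gene matrix,

$$f(g, s) \;=\; \frac{\#\{g' \neq g : \mathrm{TPM}(g', s) > \mathrm{TPM}(g, s)\}}{n - 1}.$$

Only *strictly greater* expression counts, so tied genes share a fraction,
and the denominator $n-1$ places the sample's top gene at exactly $f = 0$.
A sample's unique minimum would score exactly 1; in practice TPM data are
zero-inflated, the bottom of the ranking is tied, and all values fall in
$[0, 1)$. A zero-TPM gene keeps a well-defined fraction — the proportion of
genes expressed above zero — so no expression filter is applied before
ranking.

Because $f$ depends only on the within-sample ordering, it is invariant
under any strictly monotone transform of a sample's TPM vector, in
particular under a cohort-wide rescaling. That is the entire justification
for the processing order in `run_rankdiff()`: ranks are computed **within
each cohort's matrix first**, and only the resulting fractions are pooled.
Pooling raw TPMs first would reintroduce exactly the cohort scale effects
the method exists to remove. Raw TPMs are pooled only for the descriptive
case/control mean-TPM ratio, where an infinite value (control mean zero,
case mean positive — the `STRA8` pattern) is reported as `Inf` in TSV
output and as the infinity sign in the human-readable report, and an
undefined 0/0 ratio as `NA`.

# The bootstrap test

The test statistic for each panel gene is the absolute difference of group
mean rank fractions, $T = |\bar f_{\text{case}} - \bar f_{\text{control}}|$
(two-sided). The null distribution is generated non-parametrically: both
groups are pooled, and $B$ pseudo-datasets are drawn *with replacement*
from the pool, each split into pseudo-groups of the original sizes. The
p-value uses the add-one estimator

$$p \;=\; \frac{1 + \#\{T^*_b \ge T\}}{B + 1},$$

which cannot return zero and has resolution floor $1/(B+1)$. The floor is
the reason the default is $B = 10^5$: a claim of $p < 10^{-5}$ is only
representable at that size or above. Per-gene child seeds are derived
deterministically from the master seed and the gene's panel position, so
appending a gene to the panel never changes the p-values of the genes
before it. Bonferroni multiplicity is the panel size (five for the default
panel), not the transcriptome size, because only panel genes are
hypothesis-tested.

Resampling internals are vectorised (an index matrix per chunk of at most
5×10^6 draws, with `rowMeans`), which keeps a 5-gene panel at $B = 10^5$
and 50 samples in the low seconds and makes replicated calibration studies
practical.

# IHC scoring and the exact test

Percentage positivity is banded as: exactly 0% → `Zero` (negative); under
5% → `I`; 5–10% inclusive → `II`; strictly above 10% → `III`. The 5% and
10% boundary values fall in `II` because category I is defined as *under*
5% and category III as *over* 10%. Intensity is 1 (weak), 2 (moderate), 3
(strong), and is recorded only for positive samples. The numeric category
map `Zero→0, I→1, II→2, III→3` is the unique one whose products with
intensity fill exactly the published bands: attainable scores are
$\{0, 1, 2, 3, 4, 6, 9\}$ (5, 7, 8 are not products), banded as negative
$\{0\}$, weak–moderate $\{1\text{–}4\}$, strong $\{6, 9\}$.

Band counts per disease group (MF stage I, MF stage II/III, aggressive
CTCL) form an r×c contingency table. `fisher_exact()` computes the
two-sided Fisher / Freeman–Halton p-value by **complete enumeration**: all
tables with the observed margins are generated cell-by-cell with
feasibility pruning, and the p-value sums the multivariate-hypergeometric
probabilities of tables whose point probability does not exceed the
observed one (standard relative tie tolerance $10^{-7}$). Two numerical
choices matter. First, the accumulated probability is normalised by the
total over all enumerated tables — which is exactly 1 analytically — so
`lgamma` rounding cannot leave a degenerate single-table margin at
0.99999…; it returns exactly 1. Second, enumeration aborts above a table
cap (default 2×10^6) instead of silently approximating; biopsy-series
margins (total $N \lesssim 40$) stay orders of magnitude below it.
Correctness is cross-checked two ways in the test suite: against the
closed-form two-sided hypergeometric on 2×2 tables (to $10^{-12}$) and
against an independent implementation (`stats::fisher.test`) on r×c
tables.

By default the tested columns are only the two positive bands, matching
the layout of a printed band-count table; whether and how negative samples
enter the comparison is a reporting decision, so `include_negative = TRUE`
is provided but not default. Report cells print `k/n` with `n` the total
stained samples for that gene and group, so the two default band columns
need not sum to `n`.

# The synthetic-data generator

Every downstream stage is validated against simulated data with known
ground truth; the generator is first-class, tested code.

**Expression.** The model is hierarchical log-normal: each gene draws a
characteristic log-TPM level from
$\mathcal N(\mu_0 = 1,\ \sigma_0 = 2)$ once (shared across cohorts, so
genes keep consistent relative expression), each gene/sample value adds
independent $\mathcal N(0,\ \sigma_\varepsilon = 0.5)$ log-noise, and the
result is exponentiated. Between-gene variance dominating within-gene
noise is the realistic structure of bulk RNA-Seq — log-TPM across a
transcriptome spans several orders of magnitude while replicate samples of
the same gene vary far less — and it is also what makes mean-based
summaries of a 25-vs-25 comparison stable: a purely i.i.d. per-cell
log-normal with $\sigma = 2$ has per-draw coefficient of variation around
7, and the empirical mean ratio of a fold-20 spike would not concentrate
at these sample sizes. Cohort effects are a single global multiplicative
scale per cohort (defaults 1 and 10), sufficient to demonstrate that rank
fractions are scale-invariant — the rationale for pooling after
normalization. Differential signal is a multiplicative fold change on case
samples of spiked genes (default 20 on all five panel genes), and
testis-restricted behaviour is modelled by forcing exact zero TPM in every
control sample of designated genes (default `STRA8`), which produces the
infinite mean-TPM ratio. Default design: two cohorts of 13+13 and 12+12
samples pooling to 25 case / 25 control, $10^4$ genes. None of these
values is fitted to patient data — no distributional parameters for
patient TPMs are published — they are conventional choices for a realistic
bulk transcriptome.

What the generator does **not** emulate: count-level sampling noise (we
simulate at the TPM level), gene–gene correlation, batch effects beyond a
global scale, library-composition artefacts, and outlier samples. Passing
tests therefore demonstrate the statistical machinery behaves as specified
under its own assumptions, not that those assumptions hold for any
particular patient cohort.

**IHC.** The unit of analysis is the scored category, so the generator
draws per-(gene, group) multinomials directly over the ten outcomes
(`Zero` plus $\{I,II,III\} \times \{1,2,3\}$) — no image synthesis. The
default group sizes (19 / 6 / 7) emulate a small staged biopsy series.
Probability vectors must sum to 1 within $10^{-9}$.

All seeds are explicit config fields; generation runs under a
save-and-restore RNG guard, so identical configs are bit-identical and
library calls never perturb a caller's RNG stream.

# Validation design and problem sizes

The test suite exercises each stage against an independent oracle rather
than against itself:

* rank fractions against a quadratic brute-force exceedance count on
  random matrices up to 100×20, with heavy ties at zero;
* the bootstrap against full enumeration of all $4^4$ ordered pooled
  resamples at $n = 2{+}2$, within 3 Monte-Carlo standard errors at
  $B = 10^4$;
* bootstrap calibration: 1000 independent null replicates
  ($n = 10{+}10$ i.i.d. uniform, $B = 999$) with the empirical rejection
  rate at $\alpha = 0.05$ required to fall inside the binomial 99% band
  $(0.033, 0.070)$;
* power under the default study conditions (fold 20, 25 vs 25,
  $B = 10^5$): every panel gene must remain significant after Bonferroni;
* family-wise error on null panels: 200 replicate 5-gene runs at
  $B = 199$, clean-run rate within the binomial band of the nominal 95%;
* the exact test against the 2×2 closed form ($10^{-12}$) and
  `stats::fisher.test`, plus a 400-replicate conservativeness study under
  an identical-multinomial null.

These replicate counts and bootstrap sizes are the package's validation
design: large enough for the binomial bands to be informative, small
enough that the full suite runs in well under a minute of compute per
study.

# Known limitations

* The rank-fraction statistic compares a gene against the whole
  transcriptome, so results depend on each cohort's gene universe;
  cohorts should be quantified against comparable annotations before
  pooling.
* The pooled-null bootstrap tests the sharp null of exchangeable groups;
  it controls location differences but, like all pooled resampling
  schemes, can be sensitive to strong variance inequality between groups
  at very small $n$.
* Complete enumeration of the exact test is intentional (correctness over
  speed) and is limited to small tables; no Monte-Carlo fallback is
  provided.
* The mean-TPM ratio is descriptive, computed on raw pooled TPMs, and
  inherits cohort scale effects; inference rests on the rank fractions
  only.
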