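---
title: "Sexually antagonistic selection and X-linked expression bias under cyclical parthenogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sexually antagonistic selection and X-linked expression bias under cyclical parthenogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aphidsex)
```

## The biological question

Aphids determine sex by X-chromosome dose (XX females, X0 males) and
alternate many generations of apomictic parthenogenesis with a single
annual sexual generation. Three reproductive morphs share one genome:
asexual females, sexual females and males. Males arise by parthenogenetic
loss of one maternal X and make only X-bearing sperm, so every X in the
sexually produced offspring comes half from mothers and half from fathers
— an *autosome-like* X inheritance, unlike standard XY systems where the X
spends two thirds of its time in females.

`aphidsex` asks where sexually antagonistic mutations — beneficial to at
least one morph, harmful to at least one other — are expected to
accumulate (X versus autosomes) under this life cycle, and provides the
expression-side toolchain to test the corollary: if morph-biased gene
expression evolves to resolve such conflicts, male-beneficial alleles
accumulating on the X should leave the X enriched in male-biased genes,
and autosomes enriched in asexual-female-biased genes.

## The fitness model

A biallelic locus with ancestral allele `b` and mutant `B` affects each
morph through a selection coefficient `s` and dominance `h`:

| genotype | asexual female | sexual female | male (autosomal) | male (X) |
|---|---|---|---|---|
| `b/b` or `b/0` | 1 | 1 | 1 | 1 |
| `b/B` | $1 + h_a s_a$ | $1 + h_f s_f$ | $1 + h_m s_m$ | — |
| `B/B` or `B/0` | $1 + s_a$ | $1 + s_f$ | $1 + s_m$ | $1 + s_m$ |

Selection acts on asexual females at each of the $t$ clonal generations,
and on sexual females and males through their gamete production. For a
rare allele, frequencies grow per annual cycle by

$$\lambda_A = (1 + h_a s_a)^t \,\frac{(1 + h_f s_f) + (1 + h_m s_m)}{2},
\qquad
\lambda_X = (1 + h_a s_a)^t \,\frac{(1 + h_f s_f) + (1 + s_m)}{2},$$

because the whole male effect is exposed in hemizygous males at an
X-linked locus. Two structural consequences follow. First, for any
$0 < h_m < 1$, $\lambda_X > \lambda_A$ exactly when $s_m > 0$: the X is
*always* friendlier to male-beneficial alleles, regardless of dominance —
the opposite of the dominance-dependent rule in standard XY systems.
Second, the clonal phase raises the asexual-female term to the power $t$,
so selection in asexual females dominates the outcome, and the X-versus-
autosome contrast is carried almost entirely by $s_m$.

These closed forms are *derived*, so the package carries an independent
check: a deterministic infinite-population recursion of the full life
cycle (`expected_cycle()`, `expected_growth_ratio()`) with every random
draw replaced by its expectation. Starting the recursion from a rare
allele, the one-cycle frequency ratio matches $\lambda$ to first order;
tests assert relative agreement within $10^{-4}$, probing the limit at
$p = 10^{-7}$ where the ratio's own $O(p)$ term (which reaches $10^{-3}$
at $p = 10^{-6}$ for the strongest schemes, whose $\lambda$ is ~30) is
negligible.

## The stochastic simulator

`run_replicates()` simulates integer genotype counts through the cycle:

1. **Founding**: $N = 1000$ asexual females drawn multinomially from
   Hardy–Weinberg proportions at $p_0 = 0.005$ (~10 mutant copies).
2. **Clonal phase**: $t = 10$ generations; each female of genotype $i$
   leaves Poisson($f_a w_{a,i}$) clonal offspring, $f_a = 2$. Counts, not
   individuals, are stored, and the per-female Poissons are summed
   analytically into one Poisson per genotype class — distributionally
   exact and what makes 100,000-replicate sweeps a matter of seconds.
   The population grows to ~$10^6$ within a cycle; no cap is applied.
3. **Sexual generation**: each female bears one sexual female (a clone)
   and one male (same autosomal genome; one maternal X chosen fairly at
   X-linked loci). Gametes are Poisson with fitness-weighted means
   ($f_s = 5$); heterozygote gametes split binomially.
4. **Winter sampling**: 1000 gametes are drawn from each pool without
   replacement (multivariate hypergeometric) and paired at random to found
   the next cycle's females.

Male fecundity is morph-symmetric in the gametogenesis model but its
value is not pinned down by it; we set $f_m = f_s = 5$ (configurable).
With $f_a = 2$ and $t = 10$ a gamete pool smaller than $N$ is vanishingly
rare; such replicates are retired with the pool's own allele frequency
(0 when empty). Replicates are absorbed at loss and fixation, which is
exact (both states are closed under the dynamics) and is what lets the
vectorized engine retire most replicates early.

Relative fitnesses enter the Poisson means as the Table values themselves
(ancestral homozygote = 1), not renormalized by mean fitness: this keeps
the ancestral population's per-generation growth at $f_a$ and is the
reading under which the simulator's expectation mode reproduces
$\lambda$ — the arbiter we use for this genuinely open choice.

## Sweeps and invasion classes

`run_sweep()` draws selection coefficients uniformly on $[-0.5, 0.5]$ and
dominance per scenario (shared $h$; independent $h_a, h_f, h_m$;
sign-tied dominance $h_i = 0.75$ / $0.25$ for beneficial / deleterious
effects; $s_f = s_a$; a one-generation clonal phase; forced
$h_a = h_f = 0.5$ on the X to emulate random X inactivation; and a
standard XX/XY control). Each draw runs 25 replicates X-linked and 25
autosomal; a mutation *invades* a chromosome when its mean final
frequency after 100 cycles reaches 0.05 (ten-fold above $p_0$) and fails
to invade below 0.005. Between those thresholds we add an explicit
`indeterminate` class so that percentages at reduced draw counts remain
well defined; exclusive invasion (`X_only`, `A_only`) follows the joint
rule.

At full scale the male-beneficial summary row gives roughly 53% invading
the X, 50.2% invading autosomes and 2.2% X-only; a 2000-draw sweep
reproduces these within three binomial standard errors in seconds
(`scripts/acceptance.R` recomputes exactly this). The X-only invaders are
male-beneficial and mildly asexual-deleterious; A-only invaders are the
mirror image. One nuance the sweeps expose: when $s_f$ and $s_a$ have
opposite signs the female pathway attenuates
($((1+h_a s_a)^t (1+h_f s_f)$ close to 1) and single-location invasion
widens — so under morph-specific or sign-tied dominance a minority of
A-only invaders are driven by a *dominant sexual-female* benefit with a
recessive asexual cost ($s_a < 0$, $s_f > 0$). The sweep-property tests
assert the male-side signatures unconditionally and the asexual-side
signature where dominance is shared; for the two dominance-heterogeneous
scenarios they assert instead that every such exception is
female-benefit-driven.

The XY control (500 males, 500 females, fitness-proportional gametes,
daughters receiving the paternal X) recovers the classical picture:
male-beneficial alleles colonize the X when recessive, female-beneficial
ones when dominant. The number of generations in the control is not
dictated by the aphid protocol; we mirror it (100 generations,
$p_0 = 0.005$, 25 replicates).

## The synthetic expression study

The expression half consumes a gene×library count matrix, a
library→morph design, gene models and a marker map. `synth_dataset()`
generates all four with known ground truth, at study-like scale by
default: 8 libraries (3 male, 2 sexual-female, 3 asexual-female), 12–22
million mapped reads each, 3712 genes (13.4% X-linked), 402 markers
(14.4% X-linked) on ~300 scaffolds of which 11 are chimeric (an X and an
autosomal segment joined by a misassembly; each carries at least one
marker of each tag, which is what makes it detectable). Counts are
negative binomial (dispersion 0.05) around
`abundance × morph factor × depth`; planted bias categories are assigned
with chromosome-dependent probabilities whose defaults plant a
male-biased excess on the X and an asexual-female-biased excess on
autosomes at the magnitudes the assay should recover; planted
fold-changes are log-uniform on [2.5, 40]. A `male_x_factor` dial (1 by
default; 0.5 models an uncompensated single X) drives the
dosage-compensation analyses.

What the generator does *not* emulate: read-level errors and mapping
ambiguity (it starts at the post-mapping count matrix), gene-specific
dispersion beyond the mean trend, correlated expression between
neighbouring genes, and length-dependent counting efficiency. Passing
recovery tests therefore validate the statistical chain on its stated
generative model, not the upstream bioinformatics of a real study.

## The analysis chain

* `size_factors()` — median-of-ratios library normalization (verified in
  tests against an established reference implementation).
* `morph_effect_test()` — a negative-binomial likelihood ratio test of a
  morph-means model against an intercept model, 2 df. With 2–3 replicates
  per morph a raw per-gene moment estimate of dispersion is too noisy to
  plug into a chi-square reference (it inflates the null to ~15% of
  p < 0.05), so genes share a mean-expression dispersion trend: the
  average of per-gene moment estimates within ten log-mean bins, floored
  at $10^{-8}$. This restores null calibration (~5% below 0.05, KS
  uniformity comfortably non-rejecting across seeds) at the cost of
  assuming dispersion varies with expression level rather than gene
  identity — the documented trade-off of a deliberately simple stand-in.
  The caller is pluggable: externally computed p-values can be passed to
  `classify_expression()`.
* `adjust_bh()` — Benjamini–Hochberg step-up (delegating to
  `stats::p.adjust`).
* `classify_bias()` — the `M±F±A±` categories at fold thresholds 2, 5,
  10, on normalized per-morph means. "At least n-fold" is inclusive
  (`≥`); the 2-fold similarity clause between the two overexpressing
  morphs is strict (`<`). A zero mean in a denominator is treated as
  infinitely exceeded only by a positive numerator; two zero means fail
  the comparison. These conventions make the six categories mutually
  exclusive and nested across thresholds (verified by fuzzing).
* `assign_genes()` — genes tagged X or autosomal when their span overlaps
  a half-open window (default 200 kb, clipped at scaffold edges) centered
  on a marker; genes caught by both tags are `ambiguous` and excluded
  downstream; `window_sweep()` re-runs the assignment at 100 kb–800 kb
  and whole-scaffold mode, where the planted contrast decays as chimeric
  scaffolds contaminate wider windows. Marker positions are 0-based
  (BED), gene spans 1-based inclusive (GFF3); the package converts at the
  boundary.
* `chisq_enrichment()` / `enrichment_table()` — two-cell goodness-of-fit
  chi-square (1 df) of each category's X:A split against the baseline
  X-linkage of assigned genes supported by ≥5 normalized reads, with the
  percent deviation $100(f_X/p_0 - 1)$. No continuity correction by
  default (the headline significance survives it either way; both
  variants are exposed and tested). The unrounded baseline is used.
* `rpkm()`, `morph_rpkm()`, `dosage_tests()` — RPKM, per-morph means,
  $\log_2(\text{RPKM}+1)$, and two-sided Wilcoxon rank-sum comparisons of
  X versus autosomal genes per morph at total-RPKM thresholds (all, >0.1,
  >5), including the doubled-X male variant that models full compensation
  of the hemizygous X; `low_expression_test()` checks whether weakly
  expressed genes (<0.1 total RPKM) pile up on the X. Two caveats of the
  doubled-X comparison, visible in the synthetic tests: doubling restores
  means but not sampling distributions (at low counts a halved-mean count
  has more zeros and a higher CV, and filtering on a total the halved X
  depresses selects X genes asymmetrically), and any chromosome-dependent
  morph bias — the very signal the enrichment half looks for —
  contaminates it.

## Problem sizes and reproducibility

The test-suite and acceptance sweeps use 1500–2500 parameter draws (the
full-size study ran 200,000); at those sizes every Monte-Carlo assertion
carries a tolerance of three binomial standard errors at its own draw
count. All randomness flows through R's global generator, seeded
explicitly at every stochastic entry point; replicates advance in
vectorized lockstep, so reproducibility is per call (same seed and
arguments, same result), not per replicate. Sweep percentages at 2000
draws carry sampling noise of roughly ±1.5 percentage points on the
invasion rates.

## Limitations

Single biallelic locus only — no linkage, mutation, migration or
overlapping generations; no winter demography beyond the N-gamete
bottleneck. The differential-expression stand-in does not reproduce any
particular external caller's gene lists; analyses that depend on the real
RNA-seq libraries (total numbers of differentially expressed genes,
empirical low-expression fractions, observed expression distributions)
are outside what synthetic data can certify. Conclusions about dosage
compensation from whole-body expression inherit that caveat a fortiori.
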