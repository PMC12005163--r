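---
title: "Modelling N:S odds with baseline-and-modifier binomial likelihoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling N:S odds with baseline-and-modifier binomial likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkodds)
```

## The model

The data are per-gene variant count tables: for each gene and species, the
number of nonsynonymous and synonymous branch-specific substitutions
(`Dn`, `Ds`) and segregating polymorphisms (`Pn`, `Ps`). Every
(gene, species, context) observation — context being divergence or
polymorphism — is treated as a binomial draw: conditional on the total
variant count $N = NS + S$, the nonsynonymous count is

$$NS \sim \mathrm{Binomial}\!\left(N,\; P = \frac{\beta\alpha}{\beta\alpha + 1}\right)$$

where $\alpha$ is the *global baseline odds* — the grand-total N:S ratio
pooled over all genes, species and both contexts — and $\beta$ is a
multiplicative modifier attached to the observation's *cell*: its
combination of species, context, gene class (piRNA machinery vs all other
genes) and, optionally, subcellular compartment of the piRNA component
(nuclear vs cytoplasmic). A *partition model* is an assignment of every
cell to one of $K$ modifiers; the total log-likelihood is the gene-wise sum
of the binomial log-probabilities, and observations with $N = 0$ contribute
exactly 0 (likelihood 1), so uninformative genes never perturb the fit.

Two points deserve emphasis:

* $\alpha$ is a **fixed baseline**, computed once from the dataset's grand
  totals and never re-optimized. It is count-weighted, not an average of
  per-gene odds; genes with many variants dominate it. All inference is
  about the modifiers.
* Because every observation sharing a modifier shares the same success
  probability, the ML for each modifier is available in closed form:
  $\hat\beta_k = (\sum NS_k / \sum S_k)/\alpha$ with sums pooled over the
  parameter's observations. `fit_model()` uses this exact closed form by
  default and keeps an independent numerical route (BFGS on $\log\beta$,
  analytic gradient) for verification; the test suite requires agreement to
  $10^{-6}$ relative. The binomial coefficient is included in reported
  log-likelihoods so a single-observation likelihood matches the textbook
  binomial expression; it cancels in every likelihood-ratio test.

Degenerate pools are flagged rather than silently propagated: pooled
$S = 0$ with $NS > 0$ gives an unbounded ML (an `Inf` sentinel, flag
`nonidentifiable`, with a warning); $NS = S = 0$ leaves the modifier
uninformative (reported as 1, flagged); $NS = 0$ with $S > 0$ is the
boundary ML 0 (flagged). Flagged parameters added by a richer model are
excluded from LRT degrees of freedom, loudly.

## Hypothesis testing

Nested models are compared with the likelihood-ratio statistic
$2(\ell_{richer} - \ell_{nested})$ against $\chi^2$ with df equal to the
number of added (identifiable) parameters. Nesting is verified
structurally — every richer parameter class must lie inside one nested
class — so accidental non-nested comparisons are refused.

Model search follows a stepwise ladder: at each stage all candidate
refinements of the currently selected model are fitted, the one with the
highest likelihood is tested against the current selection, and it is
adopted only if $p$ falls below the threshold. `run_ladder()` takes
explicit candidate tiers; `select_model()` generates the candidates
automatically as all single-level splits (peel one species, split
divergence from polymorphism, split piRNA from other, split a compartment)
so that every test has df = 1. The automatic search is a reconstruction of
the tier-wise procedure; published analyses of this kind convey their exact
candidate sets graphically, so the explicit-tier interface remains the
general tool. Choices made here, deliberately:

* the adoption threshold defaults to 0.05 and is configurable; no
  multiple-testing correction is applied across ladder steps (a documented
  caveat of the stepwise approach, not a feature);
* likelihood ties between same-tier candidates break lexicographically by
  model name, making selection a pure function of (dataset, ladder,
  threshold).

## Contrast statistics and their uncertainty

For a species $i$, with cell odds $O = \hat\beta\alpha$,

$$\zeta_i = \frac{O_{div,piRNA}}{O_{div,other}}, \qquad
  \chi_i = \frac{O_{div,piRNA}/O_{poly,piRNA}}{O_{div,other}/O_{poly,other}}.$$

$\alpha$ cancels in both, and the tests assert invariance of both
statistics under rescaling $\alpha$ (to $10^{-9}$). Both can be computed
from a fit (respecting shared parameters across species) or directly from
pooled counts; under the full per-cell model the two routes coincide
exactly and the suite checks this.

Pooled odds are dominated by variant-rich genes. Two mitigations are
implemented:

* **Stratified gene-wise bootstrap.** Genes are resampled with replacement
  within the piRNA and other strata, preserving stratum sizes; each drawn
  gene carries all its species' counts jointly, preserving cross-species
  gene effects (an unlinked per-species variant is available behind
  `linked_species = FALSE`). Each replicate refits the chosen model
  structure — the preset selected structure or the full per-cell model —
  with $\alpha$ recomputed per replicate (irrelevant for $\chi/\zeta$, kept
  for internal consistency of the $\hat\beta$). Between-species contrasts
  receive one-sided sign p-values: the fraction of valid replicates whose
  contrast opposes the observed direction, zero-valued contrasts counted as
  opposing (conservative); a $+1/(B+1)$ correction is available and off by
  default. Default $B$ = 10,000; replicates with unidentifiable required
  odds are dropped and counted. The implementation precomputes gene-level
  pooled-count matrices so each replicate costs one small matrix product,
  keeping $B$ = 10,000 on genome-scale tables to seconds.
* **Weighted index.** $1/NI_{TG} = \sum_i \frac{D_{n,i} P_{s,i}}{P_{s,i}+D_{s,i}}
  \big/ \sum_i \frac{D_{s,i} P_{n,i}}{P_{s,i}+D_{s,i}}$, the reciprocal of
  the Tarone–Greenland-style weighted neutrality index. Genes with
  $P_s + D_s = 0$ are excluded and their number reported — sensible because
  species with sparse divergence otherwise flood the index with undefined
  terms; whether to refuse a whole species on that ground is left to the
  analyst, who sees the exclusion count. For a single gene with positive
  counts the index reduces to $(D_n P_s)/(D_s P_n)$, which pins the
  orientation convention.

## The synthetic-data generator

`simulate_dataset()` inverts the likelihood: per gene and species it draws
total counts for each context and then binomial nonsynonymous counts at
$P = \beta\alpha/(\beta\alpha+1)$ with the cell's true modifier. Defaults
encode the study conditions the package targets: 3 species, 31 piRNA genes
(11 nuclear, 20 cytoplasmic) among 8,747 orthologs, $\alpha = 0.308$,
$\beta \equiv 1$.

Per-gene totals are negative binomial, implemented as a per-gene gamma
intensity (size 1.2) shared across species and contexts and multiplied into
Poisson means — this yields the heavy-tailed, cross-species-correlated
per-gene counts that make gene-wise (rather than observation-wise)
resampling necessary, and reproduces aggregation pathologies such as a
single variant-rich gene dominating a pooled odds estimate
(`dataset_dominant_gene()` is a deterministic scenario of exactly that).
Mean totals default to 25 divergence and 30 polymorphism variants per gene
per species — rough figures for a ~1.5 kb *Drosophila* coding sequence with
a few percent synonymous-site branch divergence and a population sample of
10–15 strains. The true per-gene dispersion of real tables is not
derivable from summary descriptions; these defaults are stated choices, not
fits, and simulated data lack real-data features such as gene-length
variation tied to function, selection heterogeneity within a class, and
non-equilibrium demography. Passing tests on simulated data therefore
demonstrate estimator correctness and calibration, not biological claims.

Seeding: every generator takes one integer seed; per-dataset child seeds
are derived deterministically so streams are reproducible, and the caller's
RNG state is always restored.

## Problem sizes used in the test suite

The suite favours many small, fast checks: optimizer-vs-closed-form
agreement runs on 1,000 five-gene datasets; LRT type-I error and p-value
uniformity use 500 and 200 null datasets of 200 genes (~20 variants per
gene); parameter recovery uses calibration-scale simulations with pooled
counts of at least 10,000 — in practice ~60,000+ — per parameter, where the
binomial standard error of a pooled odds is comfortably below the 2%
recovery tolerance; bootstrap behaviour is checked at $B$ = 2,000 on a
full-size (8,747-gene) simulated table and at $B$ = 200–400 elsewhere.
Published modifier values appearing in tests serve as generative truth for
recovery checks, since the original variant tables are not distributed with
the package.

## Known limitations

* The model characterizes *bulk* N:S odds of a gene set, as if concatenated
  into one gene; it is not an estimate of a shared per-gene parameter and
  deliberately estimates no population-genetic quantities (no selection
  coefficients, no fraction of adaptive substitutions).
* Stepwise selection with unadjusted per-step thresholds can overfit the
  partition; the ladder report exposes every test performed so the full
  path can be audited.
* Sign-based bootstrap p-values have resolution $1/B$ and are one-sided by
  construction.
* The compartment split applies only to piRNA-class genes; datasets mixing
  labelled and unlabelled piRNA genes are accepted but the unlabelled cells
  form their own stratum of the partition.
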