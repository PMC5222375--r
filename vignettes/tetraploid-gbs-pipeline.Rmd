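---
title: "Methods: GBS genotype calling, GWAS and genomic selection in autotetraploid half-sib populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GBS genotype calling, GWAS and genomic selection in autotetraploid half-sib populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrags)
```

This vignette is the package's account of the science behind each stage:
the models, their assumptions, the tunable parameters and their defaults,
the numerical choices, and — importantly — what the synthetic-data tests
do and do not establish about real data.

## The experimental design being modelled

The package targets breeding programs in outcrossing autotetraploids
(alfalfa, *Medicago sativa*, is the motivating case) where selection acts
on **breeding values of parent plants**: each of $n$ parents is genotyped
once by GBS, and its genetic worth is estimated from the mean performance
of its open-pollinated **half-sib progeny**, grown in $c$ conditions with
$k$ replicates each (defaults $n = 154$, $c = 3$, $k = 3$, i.e. 1386
plots per trait). Marker analyses then relate the parent's genotype to
its progeny-mean phenotype.

## Genotype calling from allele read counts

GBS tags are biallelic; for each sample × marker cell the data are the
read counts of the two alleles. In a tetraploid, five genotype classes
exist (aaaa, Aaaa, AAaa, AAAa, AAAA), but at realistic GBS depths read
ratios cannot separate the three heterozygous classes reliably, so the
pipeline calls a *diploidized* code:

* both alleles observed, total depth $\ge$ `het_min_depth` (default 4)
  → heterozygote, code 1;
* a single allele observed, total depth $\ge$ `hom_min_depth`
  (default 11) → homozygote, code 2 (major) or 0 (minor);
* anything below threshold, or zero depth → missing.

The homozygote floor exists because a heterozygote can produce
monoallelic reads by chance. If each read carries the majority allele
with probability $p$, the probability that $d$ independent reads are
monoallelic is $p^d + (1-p)^d$ (`miscall_probability()`), strictly
decreasing in $d$. The worst tetraploid case is the simplex class AAAa
($p = 3/4$): at $d = 11$ the miscall probability is
$0.75^{11} + 0.25^{11} = 0.0422$, i.e. 4.22 % — the calibration behind
the default threshold. The minority term $0.25^{11}$ is negligible
($2.4\times10^{-7}$) but included for correctness.

Design choices the data cannot decide, fixed here explicitly: the
heterozygote rule uses total depth with both alleles seen at least once
and no allele-ratio test; the major allele is the more frequent one
across all samples; collapsing maps dosages $\{0\} \to 0$,
$\{1,2,3\} \to 1$, $\{4\} \to 2$.

After calling, markers missing in **more than** 30 % of samples are
removed (a marker missing in exactly 30 % is kept — call rate at least
70 %), and remaining gaps are filled by **K-nearest-neighbour
imputation** with $K = 4$. KNNI details left open by common usage are
pinned down for determinism: neighbours are samples (not markers);
distance is the mean code mismatch over co-observed markers (pairs with
no co-observed marker are infinitely distant); for each missing cell the
$K$ nearest samples observed at that marker vote, the mode wins, a mode
tie defers to the single nearest neighbour, and distance ties break by
ascending sample index. These rules make imputation idempotent and
exactly equivariant to sample permutation, which the tests exploit.
KNNI only helps when some samples are genuinely closer than others; in a
panmictic unrelated population its accuracy approaches the marginal-mode
baseline, so the corresponding test uses family-structured genotypes.

## Half-sib variance components and adjusted phenotypes

Plot values follow
$y_{icr} = \mu_c + g_i + (ge)_{ic} + e_{icr}$
with conditions fixed, progeny effects $g_i \sim (0, \sigma^2_g)$,
interactions $(ge)_{ic} \sim (0, \sigma^2_{ge})$ and plot error
$e_{icr} \sim (0, \sigma^2_e)$. For balanced data the components come
from expected mean squares:
$\hat\sigma^2_e = MS_E$,
$\hat\sigma^2_{ge} = (MS_{PC} - MS_E)/k$,
$\hat\sigma^2_g = (MS_P - MS_{PC})/(ck)$,
with negative estimates truncated to zero and flagged. Unbalanced tables
fall back to REML via `lme4` with a warning; on balanced data the two
routes agree to the optimizer's precision (the test suite verifies
agreement to $10^{-6}$ relative using a tightened bobyqa run, since
lme4's default convergence tolerance stops near $4\times10^{-6}$).

Derived statistics:

* $CV_g = 100\,\sigma_g/\bar{x}$ per condition (from the within-condition
  one-way ANOVA);
* progeny-mean broad-sense heritability across conditions
  $h^2_B = \sigma^2_g \big/ (\sigma^2_g + \sigma^2_{ge}/c +
  \sigma^2_e/(ck))$, monotone in $\sigma^2_g$, $c$ and $k$;
* type-B genetic correlation between conditions $i, j$:
  $r_g = r_p / \sqrt{h^2_i h^2_j}$ with condition-specific $h^2$ from the
  single-condition ANOVA ($\sigma^2_g/(\sigma^2_g + \sigma^2_e/k)$).
  Because the denominator is a product of estimated quantities, raw
  values beyond $\pm 1$ occur routinely; they are truncated into
  $[-1, 1]$ (the untruncated value is kept as an attribute), matching
  the capped values conventionally reported.
* **BLUP-adjusted progeny phenotypes**: grand mean plus the progeny-mean
  deviation shrunk by $h^2_B$ (the balanced-design BLUP), REML BLUPs when
  unbalanced. Shrinkage never increases a deviation and the deviations
  sum to zero. For balanced data shrinkage is a single affine map, so it
  changes no rankings — its value shows on unbalanced data, where
  progenies measured less precisely are shrunk harder.

The block structure of real field designs (incomplete blocks within
replicates) is deliberately simplified to complete randomized blocks:
block effects are orthogonal to everything the formulas above estimate,
and the package's scope is the genetics downstream of plot values.

## GWAS with genomic control

With an unstructured population (the motivating study verified absence
of subpopulation structure; the generator is panmictic by construction),
association testing is single-marker linear regression of the adjusted
phenotype on the {0,1,2} code. The squared slope t-statistic is
converted to a 1-df chi-square **exactly**, by mapping through the
$F(1, n-2)$ tail: $\chi^2 = Q_{\chi^2_1}\!\big(P_{F(1,n-2)}(t^2)\big)$.
At $n = 154$ the asymptotic identity $\chi^2 \approx t^2$ would inflate
the nominal $10^{-3}$ tail by roughly a quarter; the exact map keeps the
null statistics chi-square(1) at any sample size, which in turn keeps
genomic control honest. Monomorphic markers are flagged and excluded.

Genomic control divides all statistics by
$\lambda = \mathrm{median}(\chi^2)/0.4549$ (the null median of
$\chi^2_1$), floored at 1 so that a deflated scan is never made *more*
significant. The adjustment is monotone, so p-value rankings are
preserved. Significance uses a fixed association score
$-\log_{10}(p) \ge 3.0$ ($p < 10^{-3}$) rather than Bonferroni/FDR — the
conventional compromise for GBS marker sets where LD-aware FDR is
impractical and Bonferroni overcorrects. Per-marker $R^2$ is the squared
code–phenotype correlation.

Gene context classifies each aligned marker against GFF3 annotation,
1-based inclusive, strand-agnostic: `C` inside an exon, `I` inside the
gene span otherwise, `F` strictly closer than 3000 bp to the span, `0`
otherwise; among several flanking genes the nearest boundary wins, exact
ties go to the lexicographically smaller gene id. Markers that fail to
align to the reference genome are placed on a fictitious trailing
chromosome ("9") for Manhattan plotting, ordered by marker index.

## Genomic-prediction models

All models operate on the column-centred genotype matrix (no variance
standardization — effects stay in trait units per code unit) and expose
marker effects so that `predict()` is always
$\hat{y} = \mu + (G_{new} - \bar{G})\,\hat{u}$.

**rrBLUP.** The ridge solution
$\hat{u} = Z_c^\top (Z_c Z_c^\top + \lambda I)^{-1} (y - \mu)$ with
$\lambda = \sigma^2_e/\sigma^2_u$. REML estimation uses the equivalent
single-kernel model ($K = Z_c Z_c^\top$): after one eigendecomposition
of the intercept-projected kernel, each candidate $\lambda$ costs
$O(n)$, and a 1-D Brent search in $\log\lambda$ over $[10^{-6}, 10^6]$
(tolerance $10^{-8}$) maximizes the profiled restricted likelihood.
$\mu$ is the GLS intercept. A constant phenotype is returned as a
flagged degenerate fit with zero effects. The marker-effect and kernel
formulations agree to $10^{-8}$ on predictions — an algebraic identity
the tests assert at several $\lambda$.

**Bayes A / Bayes B / Bayesian Lasso.** Gibbs samplers (compiled, seeded
through R's RNG so chains are exactly reproducible) with the sampler
defaults: 3000 iterations, 500 burn-in, thinning 5; posterior-mean
effects over the retained draws. Priors follow the conventions of the
established whole-genome-regression software family: effect variances
are scaled-inverse-chi-square with 5 df and scale set so the marker term
explains half the phenotypic variance a priori (for Bayes B, divided by
the prior inclusion probability); the residual prior matches the other
half. Bayes B adds a point mass at zero with prior exclusion probability
`pi_zero` (default 0.5, configurable), sampling indicators from the
marginal likelihood ratio with the effect integrated out. The Bayesian
Lasso uses the exponential scale-mixture representation with an
inverse-Gaussian update for $1/\tau^2_j$ and a Gamma hyperprior on
$\lambda^2$ (shape 1, rate $10^{-3}$ — vague at the $p$-dominated
posterior scale). Divergence (non-finite state) aborts with the
iteration index; a doubled chain changes posterior-mean effects by less
than Monte-Carlo noise on the test fixture.

**SVR-lin.** $\epsilon$-insensitive linear support-vector regression via
`e1071::svm` (no feature scaling). Hyperparameters come from an
exhaustive grid over $C \in \{2^1,\dots,2^6\}$ and
$\epsilon \in \{0, 0.1, \dots, 0.9\}$ — 60 pairs — scored by 5-fold
cross-validated MSE on a seeded random 10 % subset of the training data
(the subset keeps tuning cheap; below 10 samples it falls back to the
full training data with a warning). The winning pair refits on all
training data and the primal weights are exposed as marker effects.

## Repeated k-fold cross-validation

`kfold_accuracy()` draws, per repetition, a fresh random partition into
`n_folds` near-equal folds (no stratification), refits the model on each
training split — including any tuning, so nothing leaks from the test
fold — pools the out-of-fold predictions and scores the repetition by
the Pearson correlation with the observed phenotypes. Pooling (rather
than averaging per-fold correlations) is the stable choice with folds of
~15 samples. Defaults are 10 folds × 500 repetitions; the test suite
uses 20–50 repetitions, which already stabilizes the mean to ±0.03.

Two properties of this estimator are worth knowing. First, under a
pure-noise phenotype the pooled accuracy is slightly **negative**, not
zero: each fold's predictions collapse toward its training mean, which
is anti-correlated with the held-out values (the classic fold-mean
artifact). The null test therefore asserts the absence of *positive*
skill. Second, with $p$ independent markers the ceiling on accuracy is
set by $r \approx \sqrt{n h^2/(n h^2 + M_e)}\cdot h$ with $M_e \approx p$;
at $n = 154$, $p = 2000$, $h^2 = 0.5$ this is ≈ 0.14 before any coding
loss, so low single-digit accuracies at this design scale are the
expected outcome, not a defect.

## What the tetraploid→diploid collapse costs

Collapsing dosage 0..4 to {0, 1, 2} merges the three heterozygote
classes, which at intermediate allele frequencies hold most genotypic
variance (at major-allele frequency 0.7, ~73 % of samples land in the
single heterozygote code). Truth simulated on the dosage scale and
predicted from collapsed codes loses most of its accuracy (holdout
r ≈ 0.80 on dosages vs ≈ 0.19 on collapsed codes in a
n = 100, p = 120, $h^2 = 0.9$ polygenic setting; the crossval tests pin
this contrast). The collapse is nevertheless the faithful
representation of what a depth-limited GBS pipeline can call. Passing
recovery tests on synthetic data therefore demonstrates the statistics
are implemented correctly — they do not promise real-data accuracy
beyond what this information loss and the $M_e$ ceiling allow, and the
modest accuracies reported for real populations of this design are
consistent with both.

## The synthetic-data generator

`sim_config()` defaults are the study conditions the package targets:
154 genotypes × 10⁴ markers, minor-allele frequencies uniform on
[0.05, 0.45] (post-discovery GBS markers are rarely rarer), mean depth
30 (the throughput of ~2.9 M reads/sample spread over ~10⁵ discovered
loci), negative-binomial depth with dispersion 2 — GBS depth is strongly
overdispersed, and a Poisson at mean 30 would leave the call-rate filter
and KNNI with literally nothing to do — three conditions × three
replicates, target progeny-mean $h^2$ 0.5 (the middle of typical
forage-quality heritabilities) and $\sigma^2_{ge}/\sigma^2_g = 0.25$
(modest interaction, consistent with high across-condition genetic
correlations). Traits are unitless; condition means are configurable.

Dosages are binomial(4, freq) per marker — panmictic, no LD, no
population structure — giving a controllable null for GWAS and GS.
Sparse architectures assign standard-normal effects to `n_qtl` random
markers; `n_qtl = n_markers` (the default) is the polygenic case.
Heritability is calibrated **analytically**: $\sigma^2_g$ is the
binomial-variance sum $\sum_m \beta_m^2\,4 f_m (1-f_m)$ implied by the
drawn frequencies and effects, $\sigma^2_{ge}$ follows from the
configured ratio, and $\sigma^2_e$ solves
$h^2_B = \sigma^2_g/(\sigma^2_g + \sigma^2_{ge}/c + \sigma^2_e/(ck))$.
Calibrating analytically (not by rescaling realized residuals) keeps
replicate datasets independent, at the price that any single dataset's
realized $h^2$ scatters around the target. What the generator does *not*
emulate: linkage disequilibrium (no genetic map exists for the tag
markers), tetrasomic inheritance within actual pedigrees, assay-derived
phenotype error structure, and incomplete-block field effects.

## Numerical and interface choices

* Missing genotypes are `NA` in matrices, `"NA"` in TSV, `./.` in VCF
  (`0/0` = major homozygote, `0/1`, `1/1` written against REF = major
  allele).
* REML searches $\log\lambda \in [\log 10^{-6}, \log 10^6]$, tolerance
  $10^{-8}$; kernel eigenvalues are clipped at zero.
* Gibbs samplers guard $\beta^2 < 10^{-12}$ in the inverse-Gaussian
  update and stop on non-finite residual variance.
* Pipeline configuration and run manifests are YAML (an R TOML parser is
  not part of the supported stack); every stage seed derives
  deterministically from one master seed, and artifacts record a hash of
  the configuration that produced them.
* Test problem sizes are chosen so the full suite runs in a few minutes:
  recovery studies use 20–500 replicates at $n$ of 50–200 and $p$ of
  100–2000; the statements they check are calibration statements (means
  within 3 standard errors, exact algebraic identities), which do not
  sharpen with larger $n$.

## Known limitations

* No tetraploid dosage *calling* (read-ratio genotyping): the calling
  module reproduces the diploidized convention, and the attenuation
  section above quantifies what that costs.
* Single-trait models only; no multi-trait or across-environment GS.
* `gwas` assumes the unstructured-population setting; there is no
  kinship-corrected mixed-model scan, matching the genomic-control
  design it implements.
* The SVR model exposes primal weights for the linear kernel only.
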