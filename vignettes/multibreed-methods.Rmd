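---
title: "Models and methods behind multibreed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind multibreed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`multibreed` studies a question from dairy-cattle genomics: when two breeds
(a Holstein-Friesian-like and a Jersey-like population) are combined into
one reference population, how much does genomic prediction gain, and how do
the properties of the causal loci — their allele-frequency spectrum across
breeds and the distribution of their effects — shape that gain? Because the
real cow genotypes behind the original study are not public, the package
simulates populations with the statistical structure the analysis assumes
and runs the complete analysis pipeline on them. This vignette explains
every model in the pipeline, the parameters that matter, the numerical
choices, and what the synthetic design can and cannot show.

## The two-breed genotype generator

**Drift model.** Each locus receives an ancestral allele frequency $p$ from
a one-parameter Beta family: $\mathrm{Beta}(t, t)$ for shape $t \ge 1$
(symmetric, concentrating on $1/2$ as $t$ grows) and $\mathrm{Beta}(1, 1/t)$
for $t < 1$ (rare derived alleles). Per-breed frequencies then follow the
Balding–Nichols model,
$p_k \mid p \sim \mathrm{Beta}\!\big(p\,\tfrac{1-F_k}{F_k},\,(1-p)\tfrac{1-F_k}{F_k}\big)$,
with one divergence parameter $F_k$ per breed. Defaults are $F = 0.10$ for
the larger breed and $0.14$ for the smaller one, reflecting the smaller
effective population size of Jersey-like populations; both are single
numbers a user can change.

**Variant classes.** Four classes are simulated, distinguished only by
their ancestral spectrum: three potential-QTL classes with pooled average
minor allele frequencies (MAF) of about 0.122 (moderately low — roughly the
neutral expectation), 0.077 (very low) and 0.016 (extremely low), and an
ascertained SNP-panel class averaging about 0.27, mimicking the
ascertainment bias of commercial chips. The class targets refer to loci
*segregating in the pooled sample*; for the rarest class most loci drift to
fixation, so the class ships with more loci than the trait needs
(6000 by default, of which a few percent segregate at desk scale). The
shape $t$ of each class is tuned at generator-build time by a
one-dimensional search against a deterministic surrogate of the whole
sampling chain: ancestral draw, Balding–Nichols divergence, founder
binomial sampling, and one extra drift layer per pedigree generation at
$F = 1/(2N_e)$ with $N_e = 4N_mN_f/(N_m+N_f)$ computed from the distinct
sires and dams actually used. The last layer matters: with popular-sire
matings a handful of bulls dominates the offspring gene pool, and without
it the realized MAF of the rare class overshoots its target by ~30%.
Realized desk-scale values are 0.124/0.078/0.015/0.27 against targets
0.122/0.077/0.016/0.27, and the fraction of breed-specific loci rises
monotonically as class MAF falls, as it must when rare variants drift out
of one breed.

**Pedigree and gene-dropping.** Each breed has two discrete generations by
default: unrelated founders (one third of the breed) and offspring bred
dairy-style — about 10% of each generation is male, each dam is assigned a
single sire, and offspring are allocated evenly across dams, producing
full-sib families nested inside large paternal half-sib families.
Founder haplotypes are drawn independently per locus at the breed
frequencies, so the founder population carries **no linkage
disequilibrium**. Offspring genotypes arise by gene-dropping along a
genetic map of 30 chromosomes of 1 Morgan (cattle-like) with Haldane
recombination. Linked transmission is deliberate: it gives realized
relationships genuine Mendelian-sampling variance around the pedigree
expectation — the signal a genomic relationship matrix exists to capture —
while adding no population-level LD. With fully independent transmission
every deviation of G from A is marker-sampling noise, the regression of G
on A (below) would correctly shrink G back to A, and genomic prediction
would collapse to pedigree prediction.

## Trait simulation

QTL are sampled uniformly from the segregating loci of one class (100 by
default, configurable). Allele substitution effects come from one of two
models: **RANDOM**, magnitudes i.i.d. Gamma(shape 0.4, scale 1.66) — mean
effect 0.664, a heavy-tailed pseudo-infinitesimal model — or **VAR**, the
"rare allele, large effect" model $a = \sqrt{\mathrm{Var(QTL)}/(2p(1-p))}$
with $\mathrm{Var(QTL)} = 1$ and $p$ the plain pooled allele frequency, so
every QTL explains the same variance. Both models give each effect a fair
random sign, applied to the final magnitude. Effects are identical in both
breeds, so between-breed trait differences arise only through allele
frequencies. True breeding values $\sum_j a_j g_{ij}$ are rescaled once,
pooled across breeds, to mean 0 and variance 1; per-breed means of the
rescaled values are the breed effects. Phenotypes add a normal
environmental deviate with variance $(1/h^2 - 1)$ times the variance of
the breed-effect-corrected TBV; the default $h^2 = 0.8$ corresponds to a
daughter-yield-deviation-like trait and keeps accuracies high enough that
design differences are visible at small reference sizes.

## Relationship matrices

The pedigree matrix **A** comes from the standard tabular method; breeds
share no pedigree, so its across-breed block is zero. The genomic matrix is
$\mathbf{G} = \mathbf{WW}'/(2\sum_j p_j(1-p_j))$ with
$w_{ij} = g_{ij} - 2p_j$ and $p_j = \alpha\,p_{j,1} + (1-\alpha)\,p_{j,2}$
an ancestry-weighted pooled frequency. The weights come from the breeds'
inbreeding relative to the population at divergence,
$F_2 = 1 - \sum_j 2p_{j,2}(1-p_{j,2}) \big/ \sum_j [p_{j,1}(1-p_{j,2}) + p_{j,2}(1-p_{j,1})]$
(and symmetrically), with $\alpha = F_2/(F_1+F_2)$ the breed-1 haplotype
share of the ancestral population. Both matrices are rescaled to that
divergence base: $\mathbf{G}^* = \mathbf{G}(1-F) + 2F$ with
$F = F_1F_2/(F_1+F_2)$, applied to every element including diagonals, and
per breed block $\mathbf{A}^* = \mathbf{A}[1-(F_k-f_k)] + 2(F_k-f_k)$,
where $f_k$ is mean pedigree inbreeding; the across-breed block of
$\mathbf{A}^*$ is zero.

**Regression of G on A.** $\mathbf{G}^*$ is then shrunk towards
$\mathbf{A}^*$ element-wise, $\mathbf{G}_a = \mathbf{A}^* +
b\,(\mathbf{G}^* - \mathbf{A}^*)$, with $b$ estimated per relationship
class as $b = \max\{0,\, 1 - \hat v/\widehat{\mathrm{Var}}(G^*-A^*)\}$:
$\hat v$ is the marker-sampling variance of the class's elements from a
delete-one-block jackknife over ten contiguous marker blocks, and the
denominator is the empirical variance of the class's elements. Classes
follow the pedigree: across-breed pairs, four within-breed bins of pedigree
relationship ($<0.10$, $0.10$–$0.25$, $0.25$–$0.50$, $>0.5$), and
diagonals. Binning on raw pedigree relationships (not on rescaled
$\mathbf{A}^*$) keeps unrelated pairs and half sibs in separate classes;
the rescaling otherwise shifts all within-breed pairs upward by $2(F-f)$
and merges them. Two numerical choices are worth stating: the regression
has no intercept (pure shrinkage), and empty bins keep $b = 1$. In this
generator the coefficient behaves as the estimator dictates: family bins
rise with marker density (≈0.5–0.7 at 2000–5000 markers, approaching 1 in
the dense limit), while bins of pairs with no relationship variance beyond
marker noise — unrelated founders and across-breed pairs in a
linkage-equilibrium base — stay near 0, i.e. those entries revert to
$\mathbf{A}^*$. The within-breed matrix $\mathbf{G}_w$ equals
$\mathbf{G}_a$ with across-breed elements set to zero.

## The GREML model

The base model is
$\mathbf{y} = \mathbf{1}\mu + \mathbf{Z}\mathbf{g}_a + \mathbf{Z}\mathbf{g}_w + \mathbf{e}$,
with $\mathbf{g}_a \sim N(0, \mathbf{G}_a\sigma^2_{g_a})$ an across-breed
animal effect, $\mathbf{g}_w \sim N(0, \mathbf{G}_w\sigma^2_{g_w})$ a
within-breed animal effect, and one variance per component across both
breeds, expressed on the divergence-base scale through the rescaled
matrices. Model variants drop $\mathbf{g}_w$ or add breed as a fixed
effect. Selection candidates carry no phenotypes and enter only through
the relationship matrices; their BLUPs are
$\hat{\mathbf{g}} = \hat\sigma^2\,\mathbf{K}_{\cdot,\mathrm{ref}}\mathbf{P}\mathbf{y}$,
and the total genomic breeding value is $\hat g_a + \hat g_w$.

Variance components are estimated by average-information REML with
expectation-maximization fallback whenever an AI proposal leaves the
parameter space or decreases the restricted likelihood, so the
log-likelihood never decreases over accepted iterations. Convergence
requires $|\Delta\log L| < 10^{-6}$ and relative component changes below
$10^{-3}$, with 200 iterations maximum; components are bounded below at
$10^{-8}\,\mathrm{Var}(y)$ and flagged when they rest there. Two
safeguards address the structural flatness of this model (when the
across-breed block of $\mathbf{G}_a$ is nearly zero, $\mathbf{G}_a$ and
$\mathbf{G}_w$ are almost collinear and only $\sigma^2_{g_a} +
\sigma^2_{g_w}$ is identified): a sustained likelihood plateau (three
iterations with $|\Delta\log L| <$ tolerance, or ten consecutive
iterations each gaining less than $10^{-4}$, where the residual ascent
runs along the unidentified ridge and does not change predictions)
counts as converged, and an unconverged fit is polished by Nelder–Mead
over the free log-variances. A ridge of $10^{-6}$ is added to the
reference block when its Cholesky fails.

**Power profile.** `profile_lrt()` refits the model with the within-breed
variance fixed at 1, 10, 20, …, 90, 99% of the free fit's total genetic
variance (the across-breed variance taking the remainder), re-estimating
$\sigma^2_e$ and the fixed effects — re-estimation, rather than fixing
$\sigma^2_e$ too, is a deliberate choice since only the genetic split is
under test. Twice the log-likelihood drop is compared with 2.71, the 5%
point of the 50:50 mixture of $\chi^2_0$ and $\chi^2_1$ that applies when
a variance is tested on its boundary. Because the constrained fits profile
the same likelihood, their envelope is used as the maximum if a
constrained fit edges above the free fit on a flat ridge; this keeps the
statistic non-negative by construction.

## The experiment layer

`run_experiment()` fixes one panel and one candidate set per master seed,
permutes each breed's reference pool once so smaller reference designs are
nested subsets of larger ones, and crosses seven reference designs (scaled
from 2000/2000 … 0/2000 by a configurable factor; desk default one
quarter) with marker panels, QTL classes, effect models and model
variants, replicating traits ten times (the replicate-number formula
$n > z^2(1-r^2)^2/[(N-1)\,\delta^2]$ gives at most ~9.6 replicates at
$r = 0$, $N = 1000$). Marker panels are the ascertained SNP set ("full", 5000
by default), a random 10% subset ("sub10"), and both with the genotypes of
*all* loci of the QTL variant classes appended ("+qtl") — the causal
variants enter the relationship matrices exactly like markers, through the
same locus-subset argument. Accuracy is the per-breed Pearson correlation
between total GEBV and TBV over candidates only; cell summaries are means
with standard errors $\mathrm{SD}/\sqrt{n_\mathrm{rep}}$ across replicates.

Desk-scale problem sizes were chosen so a full sweep runs on a laptop:
750 individuals per breed (500 reference + 250 candidates), 5000 panel
SNPs, 19 000 simulated loci; the test suite and the acceptance script use
a further-reduced 300-per-breed version with 10 replicates.

## What the synthetic design does and does not show

The generator reproduces the *population-genetic* structure of the
original data — diverged allele frequencies, breed-specific rare variants,
ascertained markers, family relationships — but deliberately carries **no
population LD**: founder haplotypes are in linkage equilibrium, and only
within-pedigree cosegregation links markers to QTL. Consequences observed
in this package's own experiments, stated here so that readers do not
over-interpret green tests:

* Effects that flow through family structure and breed composition
  reproduce cleanly: accuracy rises steeply with own-breed reference
  size, is nearly unchanged by adding or removing the other breed, and
  across-breed-only prediction is near zero; the likelihood for splitting
  across- from within-breed variance is flat, with most replicates below
  the 2.71 threshold — both as in the original study.
* Heritability recovery is near-unbiased for the RANDOM model at
  moderately low QTL MAF (mean ≈ 0.80 at simulated 0.8).
* Effects that in real data are driven by *LD between ascertained SNPs
  and rare QTL* — lower accuracy and stronger heritability
  underestimation as QTL MAF falls, especially under the equal-variance
  model, and large gains from adding causal variants to sparse panels —
  are weak or absent here. Within a breed, linked markers track segment
  inheritance equally well whatever the allele frequency at the causal
  locus, so the accuracy penalty for rare QTL largely disappears. The
  package measures these contrasts honestly rather than forcing them; the
  marker-panel "+qtl" gains are small and positive, and the QTL-class
  orderings are not significant at desk scale.

Other limitations: two discrete generations (no overlapping generations,
pedigree inbreeding $f \approx 0$ by default), no dominance or epistasis,
no breed-specific effects or heritabilities, no genotyping error or
imputation, and a single pair of breeds.
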