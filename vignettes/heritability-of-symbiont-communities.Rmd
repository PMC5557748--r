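---
title: "Estimating heritability of symbiont community diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating heritability of symbiont community diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symh2)
```

## The problem

Reef corals host communities of dinoflagellate endosymbionts
(*Symbiodinium*, typed by the multicopy ITS-2 rDNA marker). Whether a
coral's symbiont community is under host genetic control determines
whether symbiont associations can evolve — a central question for
predicting adaptation to warming seas. `symh2` treats the community a
host carries as a quantitative trait of the host: it collapses each
sample's OTU community into a single similarity-sensitive diversity
value and estimates the narrow-sense heritability h² = V_A / (V_A + V_E)
of that value from pedigreed families, both by a Bayesian animal model
and by parent–offspring regression.

Two breeding designs are supported, mirroring how such studies are run:
a half-diallel cross (several parents crossed pairwise, no self-crosses;
offspring phenotyped as juveniles) and a maternal-only design (eggs of
known dams, sires unknown; the design of vertical symbiont-transmission
studies).

## The phenotype: similarity-sensitive diversity

For a sample with relative abundance vector $p$ over OTUs and an OTU
similarity matrix $Z$ (entries in $[0,1]$, unit diagonal), the diversity
of order $q$ is

$$
{}^q D^{Z}(p) \;=\; \Big( \sum_{i\,:\,p_i > 0} p_i \,\big((Zp)_i\big)^{q-1} \Big)^{1/(1-q)},
$$

with limits $\exp(-\sum_i p_i \log (Zp)_i)$ at $q = 1$ and
$1/\max_i (Zp)_i$ at $q = \infty$. With $Z = I$ this is the classical
Hill number (richness at $q=0$, exponential Shannon at $q=1$, inverse
Simpson at $q=2$); with $Z$ from sequence similarity, OTUs that are
nearly identical genetically count as nearly one effective type, so the
multicopy-marker artifacts that plague ITS-2 data inflate the phenotype
far less than raw richness would.

$Z = 1 - d$, where $d$ is the proportion of differing nucleotides
between aligned OTU sequences ("raw" distances): positions where both
sequences have a gap, or either has an N, are excluded from the
denominator; a gap aligned against a base counts as a difference.

**Choice of q.** The order q weights rare versus dominant OTUs; it is a
free parameter of the phenotype. The package defaults to `q = 1`
(balanced weighting, the Shannon-limit form) and computes the full
profile `q ∈ {0, 0.5, 1, 2, ∞}` via `diversity_profile()`; every report
records the q used. Heritability estimates should be read as "h² of the
order-q diversity".

**Normalization.** Counts are variance-normalized by median-of-ratios
size factors (`size_factors()`), the negative-binomial-motivated
estimator standard in count-based sequencing analysis, with a
positive-counts fallback for sparse tables in which no OTU is observed
in every sample. Factors are rescaled to geometric mean 1. Because the
diversity phenotype renormalizes each sample to relative abundances,
size factors do not alter the phenotype; they matter for the
abundance classification (principal vs background at 0.01% of total
normalized abundance, strict inequality for background; boundary values
fall to the less extreme class) and for the IGV correlation filter.

## The genetics

`additive_relationship_matrix()` builds A by the tabular method over a
topologically ordered pedigree; founders are assumed non-inbred and
unrelated, unknown parents act as unique founders. Eggs are modeled as
diploid offspring with dam known and sire unknown, so eggs of one dam
are maternal half-sibs (A = 0.25); this is the standard encoding when
the paternal contribution is unobserved, and the alternative (treating
unfertilized eggs as haploid maternal clones) is not expressible in a
numerator-relationship framework.

### The animal model

The trait of phenotyped individuals is modeled as
$y = X\beta + a + m + e$ with $a \sim N(0, A\,\sigma^2_A)$, an optional
dam-level maternal-environment effect $m \sim N(0, I\,\sigma^2_M)$, and
$e \sim N(0, I\,\sigma^2_E)$; $h^2 = \sigma^2_A/(\sigma^2_A+\sigma^2_E)$
(the maternal variance is excluded from the denominator by default — a
flag switches to the total-phenotypic-variance denominator). Priors are
inverse-gamma(0.001, 0.001) on each variance, the conventional
weakly-informative choice, and flat on $\beta$.

Sampling is by a partially collapsed Gibbs scheme in the eigenbasis of
A restricted to the phenotyped individuals (their breeding values are
marginally $N(0, \sigma^2_A A_{pp})$, so no unphenotyped relatives need
be instantiated). Each sweep slice-samples $\log\sigma^2_A$ and
$\log\sigma^2_E$ from their posterior with $\beta$ and $a$ integrated
out analytically — cheap, because the marginal covariance is diagonal in
the eigenbasis — then redraws $\beta$ (GLS), the rotated breeding values
(independent scalars), and the maternal effects with an additional
non-centered interweaving update of $\sigma^2_M$. Collapsing removes
the funnel coupling between $a$ and $\sigma^2_A$ that makes the classic
single-site cycle mix very slowly when h² is weakly identified; the
effective sample size per retained draw improves by more than an order
of magnitude, and the sampler was validated against brute-force grid
integration of the exact marginal posterior (agreement < 0.01 in
posterior mean h² at n = 12 and n = 200–500).

Two numerical conventions matter:

* **Scale.** The trait is standardized to unit variance before sampling
  and variance chains are back-transformed. h² is scale-free, but the
  inverse-gamma rate 0.001 acts as a soft floor near 10⁻³ on any
  variance; a phenotype whose total variance sits below that floor (the
  diversity values here have variance ~10⁻⁴) would otherwise have its
  variance partition dictated by the prior rather than the data.
  Priors therefore apply on the standardized scale.
* **Summaries.** The headline estimate is the posterior mode (kernel
  density, `nrd0` bandwidth), with mean, SD, and the central 2.5–97.5%
  quantile interval alongside. Under the weak prior the posterior of h²
  is strongly right-skewed and can pile mass near the boundaries in
  small designs, so mode, mean and interval should be reported
  together; the package's validation relies on interval coverage, which
  is the property that holds at study scale (the point estimate's
  sampling SD is governed by the number of families, roughly ±0.2 at 20
  families, irrespective of estimator).

**MCMC settings.** Default 60,000 iterations, 10% burn-in, thinning 25
(2,160 retained). Because the collapsed sampler's autocorrelation time
is a few iterations, shorter runs (e.g. 20,000/thin 10, the setting used
throughout the package's replicate simulations and acceptance script)
give effective sizes of several hundred and statistically equivalent
summaries; publication-scale settings (1.5×10⁶ iterations, thinning
several hundred) are available through `mcmc_settings()`.

### DIC and maternal effects

`compare_maternal_models()` fits the model with and without the
dam-level effect under the same seed and selects by DIC. The deviance
has **marginal focus**: the Gaussian likelihood of $y$ with all location
effects integrated out, evaluated per retained draw, with pD from the
plug-in at the posterior mean variances. The conditional-focus
alternative (deviance given sampled breeding values) was tested and
rejected: its DIC differences are dominated by where the chain happens
to sit on the $\sigma^2_A/\sigma^2_E$ ridge and fluctuate by hundreds
of units between identical reruns, while the marginal focus penalizes
the extra variance component by ~1 DIC unit on null data and detects
real maternal variance reliably.

Note that maternal-effect detection requires a design in which dams
recur across genetic families (e.g. a diallel); in a maternal-only
design with unknown sires, dam family and genetic family coincide and
$\sigma^2_M$ is confounded with $\sigma^2_A$.

### Regression estimators

`midparent_regression()` regresses individual offspring values on the
family midparent (h² = slope); `single_parent_regression()` regresses
offspring on dam (h² = 2 × slope). Unweighted OLS on individual
offspring is the default (family means via a flag). Estimates outside
[0, 1] are reported raw with a warning rather than truncated.

## Intragenomic variants

ITS-2 is multicopy: one genome can carry several sequence variants that
cluster as separate OTUs and are co-inherited. The three-step procedure:
(1) candidate groups = clusters of ≥ 2 OTUs on an average-linkage
dendrogram of raw distances cut at 0.03 (the 97% OTU-identity
convention; configurable); (2) within each group keep the largest subset
whose pairwise Pearson correlations of normalized abundance satisfy
|r| ∈ [0.8, 1] (strong negative correlations are kept too — reciprocal
amplification); (3) sum member counts into the most abundant member and
drop the rest, conserving per-sample totals exactly. Because variants
are shared within genomes, collapsing them moves h² very little; the
package's tests reproduce this near-invariance (shift < 0.05 on
perfectly co-inherited synthetic variants).

## The synthetic-study generator

`simulate_study()` produces complete ground-truthed studies:

* **Pedigree**: half-diallel (default 8 parents, 20 crosses × 10
  offspring) or maternal-only (default 9 dams; 11 eggs each in the
  validation studies, matching a 99-egg maternal design).
* **Trait**: infinitesimal model on a unit phenotypic-variance scale —
  founder breeding values N(0, σ²_A); Mendelian deviations 0.5 σ²_A
  (both parents known) or 0.75 σ²_A (dam only); optional dam-level
  maternal effect m²·σ²_P; residual N(0, σ²_E).
* **Sequences**: a root sequence spawns clade ancestors (3 clades,
  echoing the A/C/D clade structure of coral symbionts) mutated at half
  the between-clade divergence (default 0.2); members mutate at the
  within-clade divergence (default 0.01).
* **Counts**: each sample's expected community is a geometric series
  over 8 principal OTUs whose common ratio is a logistic function of the
  individual's latent trait (`evenness_from_latent()`, strictly
  increasing: higher trait → more even → higher diversity); 60
  background OTUs each hold an expected 0.005% share and appear in a
  Bernoulli minority of samples (per-OTU inclusion rates 0.05–0.25);
  counts are negative binomial (variance μ + φμ²) around
  library-size-scaled expectations, libraries lognormal around 20,000
  reads.

The phenotype is induced through evenness rather than by inverting the
diversity metric (which has no closed-form inverse for non-trivial Z);
fidelity is checked by contract: Spearman correlation between the
latent trait and the computed q = 1 diversity across 200 samples ≥ 0.8.
The NB dispersion default is 0.02, typical of technical amplicon
replicates; at dispersion 0.1 count noise drowns the evenness signal
and the generator would no longer transmit the trait it is supposed to
encode (Spearman ~0.74).

What the generator does **not** emulate: chimeras and sequencing error,
read-level (FASTQ) structure, taxonomic composition shifts between life
stages, environmental covariance among neighbouring individuals, and
OTU-specific dynamics beyond the single evenness axis. Passing
recovery tests on these data therefore demonstrates that the estimators
recover a heritable signal transmitted through community structure —
not that any particular real dataset has that structure.

## Validation problem sizes

The test-suite and acceptance-script simulations use the two designs at
study scale: 20 half-diallel families × 10 offspring from 8 parents
(true h² = 0.3) and 9 dams × 11 eggs (true h² = 0.6), 20 replicates
each for interval coverage, 200 phenotype-level replicates for the
regression means, 20 replicates per scenario for DIC selection, and a
101-OTU table (16 pseudo-variants in 6 groups) for the IGV procedure.
MCMC at 8,000–20,000 iterations with thinning 10 (effective sizes in
the hundreds given the collapsed sampler's short autocorrelation time);
the grid-oracle comparisons run 60,000–80,000 iterations on an n = 12
pedigree.

## Known limitations

* Gaussian animal model only; diversity values are bounded below by 1
  and can be skewed, which the model ignores (as does the standard
  practice the package reproduces).
* The IG(0.001, 0.001) prior is "non-informative" only in a loose
  sense: in weakly identified designs it places substantial mass at
  extreme h², inflating posterior means and occasionally putting the
  KDE mode at a boundary. Interval coverage remains calibrated; point
  estimates from small sib designs should be treated with caution.
* No genomic (marker-based) relationships, no inbred founders, no
  multi-trait models.
* Maternal and additive variance are inseparable in maternal-only
  designs; the package errors or reports accordingly rather than
  pretending otherwise.
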