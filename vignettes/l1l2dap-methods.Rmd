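---
title: "Methods: L1L2 regression, stability-aware model selection and SNP saturation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: L1L2 regression, stability-aware model selection and SNP saturation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l1l2dap)
```

# The problem

Quantitative traits — cell-population fractions, haemoglobin measures,
and most clinically interesting phenotypes — are continuous, polygenic,
and measured on cohorts whose members are related. Predicting such a
trait from genome-wide SNP genotypes is a regression problem with three
structural difficulties:

1. **p ≫ n with correlated predictors.** SNPs come in linkage
   disequilibrium (LD) blocks: nearby markers are near-copies of each
   other, so univariate association testing and greedy sparse selection
   both behave erratically on them.
2. **Relatedness.** Members of a family share large genomic segments. If
   relatives are split across training and test sets, the model can
   predict the trait from family membership rather than from causal
   variants, and accuracy estimates become meaningless.
3. **Selection bias.** Any choice made while looking at validation
   samples — hyperparameters, marker panels, even encodings — inflates
   the reported accuracy.

`l1l2dap` addresses these with a two-stage sparse estimator (L1L2), a
fully specified Data Analysis Protocol (DAP) with family-respecting
resampling and internal cross-validation, a model-selection rule that
trades accuracy against the *stability* of the selected marker lists,
and a *saturation* step that recovers the LD-correlated markers that
sparse selection necessarily discards.

# The L1L2 estimator

Stage one solves the naive elastic net,

$$\hat w \;=\; \arg\min_w \; \frac{1}{n}\lVert y - Xw\rVert_2^2
  \;+\; \mu \lVert w\rVert_2^2 \;+\; \tau \lVert w\rVert_1 ,$$

by proximal gradient descent: a gradient step on the smooth part
followed by coordinatewise soft-thresholding
$S_t(v) = \mathrm{sign}(v)\max(|v|-t, 0)$. The $\ell_1$ penalty produces
exact zeros (feature selection); the $\ell_2$ penalty keeps the problem
strongly convex and lets groups of correlated predictors enter together
instead of arbitrarily picking one block member.

The naive solution selects the right features but its nonzero weights
are shrunken. Stage two therefore refits by regularized least squares
(ridge) restricted to the selected support $S$:

$$\tilde w \;=\; (X_S^\top X_S + \lambda n I)^{-1} X_S^\top y .$$

$\mu$ and $\tau$ govern selection; $\lambda$ governs the bias of the
corrected weights. `l1l2()` composes the two stages and returns a
standard modelling object with `predict`, `coef`, `summary`, `plot` and
`residuals` methods.

## Normalization and standardization conventions

The exact scaling of the objective matters for interpreting
hyperparameters, so it is fixed as written above: squared loss divided
by $n$, penalties unscaled, ridge refit with a $\lambda n$ penalty.
Dividing the loss by $n$ makes $(\mu,\tau,\lambda)$ comparable across
development sets of different sizes, which a resampling protocol
requires. Columns of $X$ are standardized to zero mean and unit variance
and $y$ is centered before solving (the penalties are scale-sensitive);
weights and intercept are mapped back to the original scale afterwards,
so predictions act on raw encoded genotypes. Constant columns are left
with weight zero rather than causing division by zero.

## Solver details

* **Step size.** $1/L$ with $L$ the largest eigenvalue of
  $(2/n)X^\top X + 2\mu I$, obtained by power iteration. This
  guarantees a monotonically non-increasing objective.
* **Acceleration.** Nesterov momentum is available
  (`accelerate = TRUE`) and is used by the protocol engine; a safeguard
  step falls back to a plain proximal step whenever momentum would
  increase the objective, so the monotonicity guarantee is preserved.
* **Convergence.** Relative $\ell_2$ change of $w$ below `tolerance`
  (default $10^{-6}$) or `max_iterations` (default 10,000). Hitting the
  cap flags the model as unconverged and warns; it never aborts a grid
  sweep.
* **Degenerate models.** If $\tau$ removes every feature, the model
  predicts the training mean and scores a squared correlation of 0 —
  large-$\tau$ grid points must score, not crash.

The exactness of the solver is verified against three independent
oracles: the ordinary-least-squares closed form at
$\mu = \tau = 0$; the coordinatewise soft-threshold closed form on
orthonormal designs ($X^\top X/n = I$); and, on problems small enough
to enumerate ($p \le 12$), an exhaustive search over all supports and
sign patterns that verifies the Karush–Kuhn–Tucker conditions of the
global minimizer. The enumeration oracle is deliberately *not* the
"ridge fit per support plus $\ell_1$ cost" shortcut: that shortcut
charges the $\ell_1$ penalty to unshrunken ridge weights and therefore
systematically prefers smaller supports than the true minimizer; it is
kept only as an upper bound on the attainable objective.

# Genotype preprocessing

Genotypes are encoded additively: the value at a locus is the number of
copies of the non-reference allele (0 homozygous reference, 1
heterozygous, 2 homozygous alternate), the reference being the major
allele observed in the data. Alternative encodings (`centered_101`,
`onehot_3col`, `class_frequency`) are provided for comparison studies;
the additive code is the default throughout.

Missing calls are imputed by drawing from {0, 1, 2} with probabilities
equal to the observed genotype-class frequencies at the locus. Imputing
genotype classes (rather than two independent allele draws under
Hardy–Weinberg) preserves the marginal genotype distribution exactly,
and both readings preserve allele frequency; the class-frequency
reading is the one implemented. Imputation is deliberately simple — no
LD- or pedigree-aware modelling — because at realistic missingness
(about 0.14% of calls) the choice is immaterial to downstream accuracy,
and simplicity keeps the protocol auditable. A single seeded stream
consumed in column-major SNP order makes imputation reproducible.

# The Data Analysis Protocol

`l1l2_dap()` runs, for each of `n_resamplings` rounds:

1. **Interfamily split.** Whole families are shuffled and assigned to a
   development set until it holds `dev_fraction` of the samples; the
   remaining families are the validation set. No family ever straddles
   the boundary, and the engine asserts zero sample overlap on every
   round. The default `dev_fraction = 0.7` is the conventional choice;
   it is configurable.
2. **Internal k-fold CV** (family-respecting folds, default `k = 10`)
   over the $(\mu, \tau, \lambda)$ grid, recording per grid point the
   mean squared error and the Canberra stability of the $k$ fold-wise
   ranked marker lists.
3. **Selection in the accuracy–stability plane.** Among grid points
   with CV MSE within `mse_tolerance` (default 5%) of the minimum, the
   one with the most stable lists wins; ties break towards sparser
   models (larger $\tau$), then lexicographically. The rule is
   deterministic and invariant to grid order. A visual "maximal
   accuracy and stability" criterion admits many formalizations; this
   lexicographic one was chosen because it is reproducible and
   auditable.
4. **Validation.** The selected triple is refit on the whole
   development set and scored by the squared Pearson correlation
   between predicted and observed trait on the untouched validation
   families (a constant prediction scores 0 by convention).

Aggregates (mean and range of $r^2$ over rounds), per-round ranked
lists, and the full accuracy–stability table are returned. A
permutation control — rerunning the identical protocol on a shuffled
phenotype — should and does collapse accuracy to chance.

`bootstrap_dap()` implements the simpler baseline protocol used for
support vector regression comparisons: grid search maximizing mean
squared correlation over family-respecting 50% resamplings, then
evaluation on further resamplings of the same pool. Because selection
and evaluation share samples, its results are potentially
over-optimistic; the result object carries a `selection_bias_prone`
flag and says so when printed. The SVR itself is consumed from
\pkg{e1071} through a plugin interface (Gaussian kernel for prediction;
linear kernel when a dense weight vector is needed for ranking), never
re-implemented.

# Ranked-list stability

Fold-wise marker lists are partial: each contains only the support of
one fitted model, out of a universe of $p$ SNPs. To compare two partial
lists, each is completed to a full rank vector — listed items take
ranks $1..k$, and every unlisted feature takes the constant rank
$(k+1+p)/2$, the mean of the unoccupied positions and the per-element
expectation of its rank over uniform extensions of the partial list.
The distance between completed vectors is the classical Canberra
distance $\sum_i |a_i-b_i|/(a_i+b_i)$, whose growing denominator makes
top-rank disagreements cost more than equal-sized bottom-rank ones —
the property that makes it a good stability measure for marker lists.
The stability indicator of a set of lists is the mean over all pairwise
distances; lower is more stable.

This completion is a representative-completion scheme: it is
deterministic, metric (the test suite property-checks non-negativity,
symmetry, identity and the triangle inequality on random partial
lists), and self-consistent across the package. A known alternative
averages the *distance* over all extensions rather than using the
expected rank; because the distance is nonlinear, absolute stability
values under that scheme differ by a method constant, but model
rankings — all the protocol uses — are unaffected in practice. An
optional normalization divides by the expected distance between two
random full permutations (Monte-Carlo estimate under a fixed internal
seed) for scale-free plotting; raw values are used for selection.

# Saturation

Sparse selection keeps one representative of a correlated block and
discards the rest, yet the discarded markers are equally associated
with the trait. Saturation recovers them: a SNP is **top-ranked** when
its |weight| lies in the top 10-percentile of a resampling's weight
distribution in at least 14 of 15 resamplings (both numbers
configurable), and a SNP is **top-correlated** when its genotype
profile has |Pearson correlation| at or above a threshold (default
sweep 0.6–0.9) with a top-ranked SNP. For sparse L1L2 weight vectors
the percentile is computed over the *nonzero* weights of each
resampling — over all $p$ weights the cut would be zero and everything
would qualify; for dense baseline weight vectors the full distribution
is used. Distances to the top-ranked SNP are reported for
same-chromosome hits only (cross-chromosome correlations are retained
but have no distance), per-SNP summaries support the "at least 5
top-correlated SNPs" reporting rule, and pooled distance and weight
distributions back the threshold-sweep plots. Raising the threshold can
only remove hits, never add them.

# The synthetic cohort generator

No external download is required: `simulate_cohort()` generates
family-structured cohorts that reproduce the statistical features the
pipeline is sensitive to, with ground truth for parameter-recovery
tests. Design choices, and what they do and do not emulate:

* **Families.** Two founders per family; each offspring receives one
  whole haplotype from each founder. This one-generation nuclear-family
  model is sufficient to make interfamily splitting matter (relatives
  share long genotype stretches — the suite verifies within-family
  genotype correlation exceeds between-family, and that deliberately
  corrupting the family boundary inflates validation accuracy). It does
  not emulate multi-generation pedigrees, recombination within
  haplotypes, or population stratification beyond families.
* **LD blocks.** Each haplotype realizes a block from one seed variant
  drawn at the block's minor-allele frequency; the block's first SNP
  *is* the seed, and the remaining members are noisy copies
  (per-SNP flip probability, default 0.05). Under the default
  `ld_decay = "constant"` all members correlate equally with the seed;
  `ld_decay = "markov"` accumulates flips along the block so
  correlation decays geometrically with distance, which is the regime
  for distance-concentration analyses. Block-copy LD gives direct
  analytic control over the correlation a saturation threshold sees —
  for flip probability $q$ and seed frequency $m$ the seed–member
  genotype correlation is
  $m(1-m)(1-2q)/\sqrt{m(1-m)\,p_x(1-p_x)}$ with
  $p_x = m(1-q)+(1-m)q$, about 0.84–0.89 for $q = 0.05$ and
  $m \in [0.25, 0.5]$ — at the cost of not being a coalescent
  simulation.
* **Trait architecture.** One causal SNP per chosen block (the seed
  member), with random signs and geometric magnitudes
  ($0.8^{j}$ by default). The heavy-tailed profile — a few major loci
  plus a polygenic tail — matches what mapping populations actually
  show for traits like haemoglobin measures, and it is what makes a
  heritability-0.3 trait partially recoverable at cohort sizes of a few
  hundred: with twenty equal effects at $h^2 = 0.3$, each variant
  explains ~1.5% of variance and even an oracle fit on the true support
  validates poorly. Noise variance is set so the realized genetic
  variance fraction matches the requested heritability (calibration is
  property-tested: mean realized $h^2$ within 0.03 of target over 50
  replicate cohorts).
* **Missingness.** Uniform masking at rate 0.0014, mirroring realistic
  genotyping-chip missingness.

Because cohorts are generated, passing tests demonstrate correctness of
the machinery and sane behavior under the modelled structure; they do
not certify accuracy levels on real genotyping data, where LD is
irregular, effects are unknown, and missingness is informative.

# Problem sizes used by the test suite

The verification suite fixes its problem sizes as part of the study
design: the end-to-end protocol runs on the reference cohort of 600
samples (100 families of 6) by 2,000 SNPs at $h^2 = 0.3$ with 5
development/validation resamplings, 5-fold internal CV and a 12-point
grid ($\mu = 10^{-2}$; four $\tau$ values spanning supports from
hundreds of SNPs down to a few dozen; $\lambda \in \{10^{-2}, 1,
10^2\}$); solver–oracle equivalence uses 50 random instances with
$p \le 12$, $n \le 40$; the saturation checks use cohorts of 900
samples with 300–400 SNPs. The reference cohort (generator seed 101)
is the same cohort on which the generator's effect-size profile was
calibrated; on it the protocol attains a mean validation $r^2$ of about
0.21 while the permutation control sits below 0.01.

# Known limitations

* The completion constant of the Canberra partial-list distance is a
  package convention; compare stability values only within one scheme.
* The additive encoding's reference allele is data-derived (major
  allele), so datasets with allele frequencies near 0.5 can flip codes
  between reads; this changes signs, not fits.
* The bootstrap baseline protocol is implemented as family-respecting
  50% subsampling; it is labelled biased by construction and should
  only serve as a comparison point.
* Imputation ignores LD and pedigree; at high missingness rates a
  dedicated imputation tool should replace it upstream.
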