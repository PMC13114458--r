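---
title: "Methods: radiomic-pathway association in zone-resolved glioblastoma data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomic-pathway association in zone-resolved glioblastoma data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

radpath links two views of glioblastoma heterogeneity: transcriptomic
programs scored from laser-microdissected anatomic zones (cellular tumor
CT, microvascular proliferation CTmvp, pseudopalisading necrosis CTpan,
infiltrating tumor IT, leading edge LE) and radiomic features computed
from MRI subcompartments (enhancing tumor ET, non-enhancing tumor NET,
peritumoral edema ED). Because no voxel-level registration links
microdissection sites to MRI, the zones are mapped to subcompartments
biologically (CT and CTmvp to ET, CTpan to NET, IT and LE to ED), and all
associations are zone-approximate. The package implements two
complementary inferential frameworks over this mapping — an exploratory
linear mixed-effects analysis at the patient-by-subcompartment level and
a leakage-free predictive analysis at the patient level — together with
the permutation and multiplicity machinery both need, and a synthetic
cohort generator that reproduces the statistical structure of the design
so every stage is testable without the original data.

## Pathway scoring

Expression arrives as FPKM and is transformed to `log2(FPKM + 1)`.
Single-sample enrichment scores are rank-based running sums: within each
sample, genes are ranked in decreasing order of the per-sample statistic
and the score of a set is the sum over rank positions of the weighted
cumulative in-set fraction minus the unweighted cumulative out-of-set
fraction. Two documented choices:

* **Weights.** The in-set weight at a rank position is the descending
  rank statistic raised to `weight_exponent` (default 0.25, the usual
  single-sample enrichment convention; 0 gives the unweighted score).
  Because the weight derives from the rank rather than the raw value,
  the score with the kernel transform off is a pure rank statistic,
  exactly invariant to any strictly monotone per-sample transform — a
  property the test suite asserts.
* **Kernel transform.** An optional per-gene Gaussian-kernel CDF across
  samples (bandwidth `sd/4`) applied before ranking (default on). It is
  monotone per gene but changes the cross-gene ordering within a sample,
  so it is exposed as a flag rather than hard-wired; large simulation
  experiments in the test suite disable it for speed since it does not
  change the properties under test.

Scores are optionally normalised by the global score range (default on);
downstream z-scoring makes every analysis invariant to this within a
pathway. Ties in expression are broken stably by gene id so scores are
identical across platforms.

Zone-specific gene modules are derived per zone by a two-sided Wilcoxon
rank-sum test of each gene in-zone versus all other zones on the log2
scale, Benjamini-Hochberg adjustment across genes, retention at
FDR < 0.05 and absolute difference of mean log2 expression above 1,
ranking by ascending FDR (ties: descending effect, then gene id), and
truncation at `top_k = 200`. The fold-change filter is defined as a
difference of means on the log2 scale because a ratio of means is
ill-defined with zeros. The Wilcoxon p-value uses the tie-corrected
normal approximation with continuity correction (verified against
`stats::wilcox.test` in the tests). Modules derived from the same
expression matrix that is later scored are circular by construction;
they are useful as internal-consistency checks, never as independent
evidence, and the package treats them as ordinary gene sets while the
reporting keeps their category label (`ivygap_module`) visible.

## Zone mapping and aggregation

Replicate microdissection samples within one patient-zone are averaged
first, so patients with more replicates do not dominate; the available
mapped zones are then combined per patient and subcompartment by the
map's aggregation function (mean by default, median for the S3 variant).
Each observation records its composition (which zones contributed).

The composition baseline test guards against a pathway "signal" that
merely tracks which zones happened to be available: it is the Spearman
correlation between the patient-level score and a numeric composition
indicator. The indicator is not uniquely determined by the design, so
the default is the number of distinct contributing zones, with a binary
CTmvp-availability indicator as the documented alternative — the
motivating concern is that the ET score is CT-only for some patients and
mean(CT, CTmvp) for others.

## Radiomic feature reduction

Three stages, in fixed order:

1. **Near-zero variance.** `caret::nearZeroVar` with its published
   defaults (frequency ratio 95/5, unique percentage 10).
2. **Correlation pruning** at |Spearman| > 0.90. The common greedy
   heuristic depends on column order; radpath instead repeatedly finds
   the worst offending pair and drops the member with the larger mean
   absolute correlation to all retained features (ties: the
   lexicographically larger id). The result is order-invariant and all
   surviving pairs satisfy the bound.
3. **Supervised univariate screen** (the only stage that sees the
   outcome): per-feature Spearman correlation with the pathway score,
   BH adjustment within each subcompartment, eligibility at minimum
   FDR < 0.10 across subcompartments, ranking by minimum raw p (ties by
   feature id) and a cap of 5 features per pathway. An empty selection
   is a valid outcome — such pathways enter the association campaign at
   p = 1. In the predictive analysis the same screen runs *inside each
   cross-validation fold* on training patients only.

Spearman p-values use the tie-corrected t approximation, with the exact
permutation distribution for n of at most 9 without ties, so tiny
subcompartments (ED has 7 patients) are handled reproducibly.

## Mixed-effects association

For each pathway with at least one screened feature, the full model is

```
z_pathway ~ z_rad_1 + ... + z_rad_k + subcompartment + (1 | patient_id)
```

and the null model drops the radiomic terms. The response is globally
z-scored; the features are z-scored within subcompartment (globally
under the S7 variant). Both models are fitted by maximum likelihood with
lme4; the omnibus radiomic contribution is the likelihood-ratio
chi-squared with k degrees of freedom, floored at zero. Marginal and
conditional R2 follow the Nakagawa-Schielzeth decomposition, with the
fixed-effect variance computed as the population variance of the fitted
fixed-effect predictor over the analysis rows; the intraclass
correlation comes from the null model. The increment `delta_r2m` is a
difference of marginal R2 between full and null models and can be
slightly negative because the decomposition is not strictly additive —
the package reports it as-is.

Per-coefficient inference uses the Wald normal reference with Holm
correction across the k radiomic terms, and the intervals are labelled
Wald intervals; omnibus inference rests on the LRT, so
denominator-degrees-of-freedom approximations (Satterthwaite,
Kenward-Roger) are intentionally out of scope. Covariate adjustment
refits both models with the covariates included in each (models A-D:
none; age; age + MGMT; age + MGMT + subtype), so the LRT always isolates
the radiomic contribution; the subtype factor at small n is reported
with its convergence flag. Exact leave-one-observation influence refits
and a Shapiro-Wilk check on conditional residuals are available as
diagnostics and are never asserted as pass/fail.

Across pathways, the conservative family-wide correction pads the BH
family to the full number of scored pathways by assigning p = 1.0 to
pathways with no surviving features. This inflates the denominator and
is deliberately conservative; it is not a formal FDR guarantee since the
placeholders are not p-values under the null. The standard BH correction
restricted to the tested pathways is always reported alongside.

## Nested predictive analysis

Scores and features are averaged across each patient's available
subcompartments (median under S3), the patient-level score is z-scored,
and a leave-one-patient-out loop runs: screen on the training patients,
fit an elastic net on the selected features, predict the held-out
patient. The elastic net minimises
`(1/2n) RSS + lambda (alpha L1 + (1-alpha)/2 L2)` with features
standardized on training statistics; for each alpha on the grid (0.1 to
1.0 in steps of 0.1) the inner five-fold cross-validation error curve is
computed over the lambda path of the full training fit, alpha is chosen
by the minimum curve value (ties to the smaller alpha, favouring the
ridge end), and lambda by the one-standard-error rule at that alpha. The
inner folds are assigned deterministically by blocking observations on
the rank of the response and permuting fold labels within blocks with a
seeded generator, so every fold assignment is reproducible at n = 27.

Folds that select no features predict the training mean: the pooled
metric stays defined and empty models are naturally penalised (they
drive the cross-validated R2 to zero or below), which is how no-signal
pathways are reported. Pooled metrics use all held-out predictions with
the overall observed mean in the denominator; MAE is on the analysis
(z-scored) scale and labelled as such. Stability is the fraction of
folds selecting a feature; above 0.5 a feature is stability-selected.
Bootstrap percentile intervals for the cross-validated R2 resample
(observed, predicted) pairs with replacement; they condition on the
fitted predictions and quantify metric sampling variability only.

The legacy comparator runs the same loop with the screen executed once
on all patients before the loop. Its apparent (in-sample) R2 is also
recorded, because that is the quantity full-data selection inflates; the
contrast with nested cross-validation is the package's built-in
demonstration of selection leakage.

## Permutation inference

Two frameworks, both one-sided (large statistics are extreme) with
p = n_extreme / N by default; an observed value exceeding every null
gives p = 0, matching the convention that makes values such as 0.055
and 0.050 representable at N = 1000, and `(n+1)/(N+1)` smoothing is
available behind a flag.

* **Patient-level (mixed model).** A random patient permutation moves
  each patient's pathway-score rows together onto another patient's
  rows, matched by subcompartment; rows without a counterpart are
  dropped for that permutation, and permutations losing more than half
  the rows are redrawn (counted). Features stay fixed at the
  pre-selected set, so this null does not account for adaptive
  selection — which is exactly why the fully nested framework exists.
* **Fully nested (predictive).** Pathway scores are shuffled across
  patients and the entire nested loop, including the in-fold screen, is
  re-executed per permutation. The permuted reruns reuse the observed
  run's seed so the identity permutation reproduces the observed
  statistic exactly.

Two properties of this machinery emerged from the calibration
experiments and are worth knowing. First, patient-level averaging
couples the dispersion of scores and features through the availability
pattern: a patient with one subcompartment is noisier on both sides, so
with unbalanced availability the observed alignment is not exchangeable
with permutations even in the absence of any true coupling. The
calibration null therefore uses balanced (iid) tables, and real-data
permutation p-values should be read with this caveat. Second, under the
FDR-gated screen a null pipeline usually selects nothing, the permuted
R2 distribution carries a large atom at the mean-predictor value, and
the `n_extreme/N` convention with ties counted as extreme makes the
p-value conservative rather than uniform; uniformity holds in the
continuous regime where a model is fitted in every fold. The acceptance
suite checks uniformity in the continuous regime (forced selection) and
checks that the gated regime is never anticonservative.

## Sample-size criteria

The four published minimum-sample-size criteria for a continuous-outcome
prediction model are implemented directly: (1) expected shrinkage at
least S, `n = p / ((S - 1) ln(1 - R2/S))`; (2) apparent-vs-adjusted R2
difference at most delta, `n = 1 + p (1 - R2) / delta`; (3) residual-SD
precision within a 10% multiplicative margin, `n = 234 + p + 1` — the
published tabulated degrees of freedom are used (a direct solve of the
chi-squared margin inequality gives 233, but 234 is the criterion as
published and is what reproduces the reference value of 240 at p = 5,
R2 = 0.20); and (4) precise mean predicted outcome, which needs the
anticipated outcome mean and SD and is reported as not applicable for a
standardized (mean-zero) outcome. The minimum detectable R2 at a given n
inverts the R2-dependent criteria (1 and 2) by bisection; the criterion
set behind published inversions of this kind is ambiguous, so the
package reports its own inversion and documents the definition rather
than matching any particular printed value.

## Sensitivity variants

Variants are pure configuration deltas: S1a (ET = CT only), S1b
(shipped alternate map assigning CTpan to ET; the design names the
variant but not its mapping, so the mapping is config, not doctrine),
S2 (exclude patients contributing a single subcompartment), S3 (median
aggregation), S4a (FDR family restricted to the Hallmark sets), S7
(global feature standardization), and S9 (alias of covariate model D).
S4b/S4c (subset definitions not specified in the main text) and S6/S8
(random slopes, Kenward-Roger) are declared stubs that fail loudly.
Rerunning the base configuration after any variant reproduces base
results exactly — the variant machinery holds no state.

## The synthetic cohort generator

The generator reproduces the statistical structure the analysis assumes,
with defaults fixed at the motivating design: 28 patients; CT sampled in
all, CTmvp in 9, CTpan in 15, and 7 patients with an IT/LE sample of
whom 6 also carry CTpan — yielding 50 patient-by-subcompartment
observations (ET 28, NET 15, ED 7) with 6 of 28 patients covering all
three subcompartments. Age is Normal(58.5, 7.8) truncated to [30, 85]
and MGMT methylation is Bernoulli(13/28), matching the reported cohort
moments. Expression is generated on the log2 scale — per-gene Gaussian
baselines, a per-set per-zone shift (SD 1) giving the zone-differential
structure, and a per-patient latent pathway activity (SD 1) shifting all
genes of a set in all of that patient's samples — then back-transformed
via `2^x - 1` truncated at zero, so the scorer's `log2(FPKM + 1)`
recovers the generative scale. Radiomic tables contain iid features
around a per-patient intercept (SD 0.5, the source of a nonzero
downstream ICC), near-zero-variance columns, correlated blocks
(pairwise correlation about 0.95), and planted couplings
`beta * activity + intercept + noise`; a coupling may be declared by a
target signal-variance fraction f, from which
`beta = sqrt(f/(1-f) (sigma^2 + patient_sd^2))` at the row level. All
randomness derives from one integer seed through a labelled hierarchical
hash, so any component regenerates in isolation.

What the generator does not emulate: spatial autocorrelation of real
radiomic features, heavy-tailed and batch-structured feature
distributions, nonlinear pathway-feature links, treatment effects, and
any genuine image content. Passing tests therefore show that the
pipeline recovers what it assumes — linear couplings under the stated
noise model — not that the biological claims of any particular dataset
are correct.

## Numerical choices and problem sizes

Ties and degeneracies are handled deterministically throughout: stable
gene-id tie-breaks in ranking, lexicographic tie-breaks in pruning and
screening, degenerate responses short-circuited (a constant response
yields chi-squared 0 and p 1; a zero-variance training response yields
the intercept-only model), and zero-variance bootstrap resamples redrawn
and counted. Mixed models use `lmerControl(calc.derivs = FALSE)` with
convergence messages captured into a flag; non-converged fits enter the
FDR set at p = 1. The test suite exercises the stochastic properties at
reduced but statistically safe sizes chosen as the package's own
simulation design: 1000 null mixed-model fits for type-I calibration,
200 replicates at 99 permutations for permutation calibration (12
patients, forced selection, fixed penalty so the experiment fits one
CPU), 10 replicates at 200 patients for planted-signal recovery (mean
cross-validated R2 asserted within [0.35, 0.60]), and 8 null cohorts
with 200 candidate features for the leakage contrast. The large
simulation tests disable the kernel transform and use a 3-point alpha
grid; both are configuration flags whose default study values remain the
full grid and kernel on.

## Limitations

The package inherits the design's structural limits: the
zone-to-subcompartment mapping is biologically motivated, not spatially
registered, so all associations are attenuated by an unknown amount; at
28 patients the predictive analysis is far below the
minimum-sample-size criteria it itself computes (N_min = 240 for the
intended effect size), so cross-validated estimates are unstable by
construction; zone modules scored on their source expression matrix are
circular; and the conservative padded FDR is a reporting policy, not a
guarantee. The permutation caveats above (availability-driven
non-exchangeability, atom-induced conservativeness) apply to any use of
the patient-level permutation on unbalanced designs.
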