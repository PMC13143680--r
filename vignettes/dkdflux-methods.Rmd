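---
title: "Methods: digital urine physicalomics and serum-to-urine flux ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital urine physicalomics and serum-to-urine flux ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures it implements, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where more than one reasonable option existed.

## The problem

Screening for diabetic kidney disease rests on eGFR and the urine
albumin-to-creatinine ratio (UACR). Both are late readouts: eGFR falls only
after substantial histological damage, and albuminuria misses the
increasingly common non-albuminuric phenotype. Two earlier signals motivate
this package. First, proximal-tubule secretory failure changes how solutes
partition between serum and urine before filtration markers move; for
protein-bound uremic toxins cleared by organic anion transporters (indoxyl
sulfate, p-cresyl sulfate, phenylacetylglutamine) this produces a
"high serum / low urine" mismatch. Second, surfactant proteins leaking into
urine change its macroscopic physics — foam that persists, smaller bubbles —
and loss of concentrating ability changes its colour. Both signals are
quantifiable with commodity hardware.

## Serum-to-urine flux ratio

For metabolite $m$ in a paired sample,

$$\mathrm{flux}_m \;=\; \log_{10}
\frac{[C]^{\mathrm{serum}}_m / [C]^{\mathrm{serum}}_{\mathrm{creat}}}
     {[C]^{\mathrm{urine}}_m / [C]^{\mathrm{urine}}_{\mathrm{creat}}}$$

with all concentrations in µmol/L. Creatinine normalisation in each fluid
makes the ratio exactly invariant to uniform dilution of either fluid and to
any concentration unit applied consistently — the two invariances the test
suite asserts exactly. The pipeline order is fixed:

1. **Missingness filter** — a metabolite is dropped when its missing
   fraction strictly exceeds 20% in *either* fluid. Censored (below-LOD)
   entries are not "missing": they carry information and are handled later.
2. **KNN imputation** (k = 5) of the remaining missing-at-random values:
   Euclidean distance over z-scored log10 concentrations of the features
   observed in both subjects, censored entries provisionally valued at
   LOD/2 for distance purposes, ties broken by subject order so the result
   is deterministic. The mean squared distance is used so subjects with
   different overlap are comparable. k and the metric are not dictated by
   the underlying method; k = 5 is the metabolomics default.
3. **LOD/2 substitution** of censored values, flagged in the provenance
   table, which keeps the logarithm finite while acknowledging the value is
   below detection.

Imputation runs per fluid: serum and urine concentrations of the same
metabolite differ by orders of magnitude, and cross-fluid neighbours would
be dominated by that offset.

**Dilution normalisations.** For global (non-ratio) urine matrices two
corrections are provided. PQN divides each sample by the median of its
feature-wise quotients against a reference spectrum. The orthogonal
"creatinine-adjusted total useful signal" (TUS) correction is named but not
defined by any formula in the literature this package follows; we define it
as division by $\sqrt{\mathrm{TUS}_i \cdot \mathrm{creat}_i}$ — the
geometric mean of the sample's total retained-feature signal and its
urinary creatinine. Both factors scale linearly with urine dilution, so the
normalised profile is *exactly* dilution invariant, while the geometric mean
hedges the pure total-signal correction against the asymmetric global
signal shifts severe disease induces (the known PQN/TSN failure mode). The
plain alternative (divide by total signal only) is also dilution invariant
but ignores creatinine entirely; the concordance check
(`normalization_concordance()`) quantifies how little the downstream feature
selection depends on this choice.

## Physicalomics extraction

**Colour.** An affine 3×3 + offset transform is fitted by least squares from
the observed in-frame card patches to their reference sRGB values (≥ 4
patches required; the design must have full rank). Post-correction colours
are treated as sRGB with D65 white and converted to CIELAB with standard
companding; the capture illuminant is assumed removed by the card
correction, which is exactly the card's purpose. Yellowness is
dilution-corrected to a 650 mOsm/kg reference urine:
$b^*_{adj} = b^* \times 650/\mathrm{osmolality}$, the identity at 650.

**Foam.** Heights are measured on a binary foam mask (luminance threshold
0.5 inside the foam ROI, disc opening/closing of diameter 3 px against
speckle) as the column-wise vertical extent summarised by the median — the
median because "height" is not operationally defined by the source method
and a median resists stray bright pixels. T₁/₂ comes from a two-parameter
least-squares fit of $\log_2 h$ against time rather than interpolation
between frames: only four protocol time points exist and the decay framing
is explicitly exponential. Foam that never halves within the window and
whose fitted half-life exceeds the last frame time is flagged right-censored
and reported as a bound ("> 120 s"), so downstream models can cap rather
than receive an infinity.

**Bubbles.** Bubble caps are segmented inside the foam mask (luminance
> 0.8), split along distance-map watershed ridges, and labelled; each
component's equivalent-circle diameter is $d = 2\sqrt{A/\pi}$ (the source
says "diameter" without a shape convention; the equivalent circle is the
standard granulometry choice). MBI is the percentage of the *total foam
mask* area — interstitial pixels included — occupied by components with
d < 0.5 mm. An empty foam mask yields `NA` with a warning, deliberately
distinct from a genuine 0%.

**Validation statistics.** CV% = 100·SD/mean per feature (undefined at mean
zero, signalled); Bland-Altman bias, 1.96·SD limits of agreement, and the
share of differences inside them.

## OPLS-DA, VIP and permutation validation

The discriminant model is a NIPALS O-PLS with one predictive component:
class-orthogonal variation is deflated (default one orthogonal component;
with `n_ortho = NULL` components are added while cross-validated Q²
improves by more than 0.01, capped at five, since the source models do not
state their component count), then the predictive component is fitted on
the deflated matrix. Columns are centred and unit-variance scaled
internally; constant columns get unit scale. R²Y is the explained class
variance; Q² is computed by 7-fold cross-validation (the conventional
default for this model family) with fold assignment controlled by a seed.
With one predictive component the VIP reduces to $\sqrt{p}\,|w_j|$ with
unit-norm weights, which makes the normalisation identity mean(VIP²) = 1
hold to machine precision — the suite asserts it on every fit.

Permutation validation refits under label permutations and applies the
two-condition rule: all permuted R²Y and Q² below the originals, and the
intercept of the Q²-versus-label-correlation regression (the validation-plot
line, which includes the unpermuted point at correlation 1) below zero.
Differential features require VIP > 1.0 *and* Benjamini-Hochberg FDR < 0.05
from Mann-Whitney (two groups) or Kruskal-Wallis tests.

## Fusion classifier evaluation

Three nested tiers are compared: clinical base (age, BMI, HbA1c, SBP), the
metabolomics tier adding the top flux markers (indoxyl sulfate,
C8-carnitine, phenylacetylglutamine), and the fusion tier adding the digital
urine phenotypes (T₁/₂, b\*). Evaluation is repeated stratified k-fold
cross-validation (default 10 × 5) of probability random forests (500
trees). When feature selection is requested it is RF-RFE — drop the
lowest-importance 20% of remaining features per round, importance being
permutation importance averaged over inner CV folds — re-run inside every
outer training fold, so held-out folds never see the selection. The forest
size, drop fraction and inner-fold count are conventional defaults, not
prescribed values. Out-of-fold probabilities are averaged per subject over
repeats and pooled; that vector yields the cross-validated AUC with DeLong
confidence interval, and the calibration metrics. Apparent performance is
the full-data forest predicting its own training set, reported separately so
the optimism (apparent − cross-validated) is visible; a negative optimism
triggers a warning rather than an error since it can legitimately occur by
chance on null data.

Calibration: Hosmer-Lemeshow on risk deciles (tied or empty groups merged
with a warning; constant predictions collapse to one group and an undefined
test), calibration slope from the logistic recalibration of the outcome on
logit(prediction), intercept from the offset model, Brier score as the mean
squared error. NRI is the continuous (category-free) variant — no risk
categories are prescribed anywhere upstream — and IDI the difference of mean
risks; both get seeded percentile-bootstrap CIs (1000 replicates).
Decision curves use $NB(\tau) = TP/N - (FP/N)\,\tau/(1-\tau)$ against
treat-all and treat-none. The nomogram maps an additive logistic fit to a
0-100 points scale (reference = each feature's lowest-risk end, scale set by
the widest-range feature); because the model is additive the
points-to-probability round trip is exact up to floating point, and the
suite requires < 0.5% everywhere.

Sample-size helpers implement the Riley minimum-n criterion
$n = p / ((S-1)\ln(1-R^2_{CS}/S))$, the Hanley-McNeil SE of an AUC, and
events-per-variable. Evaluating the Riley formula at p = 15,
R²CS = 0.25, S = 0.9 gives 461; a published application of the same formula
reports "approximately 255" for those inputs, which does not reproduce — the
package reports the formula's value.

## Prognosis

MARE is a composite of sustained relative eGFR decline, macroalbuminuria
onset (UACR strictly > 300 mg/g) and ESRD. "Sustained" is operationalised as
the decline threshold met at two consecutive visits, with the confirming
visit as the event time — the usual trial convention; the source never
defines it. The decline threshold is a parameter defaulting to 30%: the
governing methods text uses ≥ 30% while a summary table footnote uses 40%,
and the methods definition wins, with the 40% variant available by
configuration. Risk strata split at a score of 0.5, boundary inclusive into
"high". The Monte-Carlo projection draws each subject's event once per
iteration (default 1000) and summarises stratum rates with percentile
intervals; its convergence to the analytic mean is asserted within three
Monte-Carlo standard errors. The Cox wrapper uses Breslow ties so that with
no competing events it coincides exactly (the suite demands 1e-6 relative)
with the Fine-Gray model, which is fitted by `cmprsk::crr` with a tightened
gradient tolerance (1e-10, relaxed stepwise only if the optimiser stalls).

## What the synthetic-data generator emulates

`generate_cohort()` draws, per group (80 healthy controls, 102 T2DM without
kidney disease, 100 DKD by default), the published baseline summaries:
Gaussian marginals for mean ± SD variables, log-normal marginals for
median (IQR) variables — parameterised so the printed median and quartiles
are matched, with the IQR taken symmetric on the log scale, which preserves
skew and positivity (for UACR's strongly asymmetric printed IQR this is an
assumption, not a statement of the source). Dependence is a Gaussian copula.
Four couplings are reported upstream: T₁/₂ vs log-UACR (r = 0.78), b\* vs
osmolality (r = 0.78), MBI vs log-UACR (r = 0.85) and surface tension vs
T₁/₂ (Spearman ρ = −0.88, converted to its latent correlation by
$2\sin(\pi\rho_s/6)$). Pairwise zero-fill of the remaining entries is not
positive definite — r(T₁/₂, UACR) and r(UACR, MBI) jointly force a large
T₁/₂-MBI correlation — so the correlated block is closed by a single latent
severity factor whose loadings (0.90, 0.867, 0.981, −0.988) reproduce the
four stated pairs exactly and imply the other three (T₁/₂-MBI 0.883,
UACR-γ −0.856, MBI-γ −0.969). Correlation targets for log-normal variables
are defined on the log scale: with T₁/₂'s log-SD of ≈ 1.09 the maximum
achievable raw-scale Pearson correlation with a normal variate is ≈ 0.72,
so a raw-scale target of 0.78 would be unattainable, and correlating such
skewed quantities on the log scale is standard practice anyway. Surface
tension is not tabulated upstream; its group means (66/62/52 mN/m, healthy
urine near water-like values and proteinuric urine markedly lower) are the
package's one free choice of marginal, fixed once here.

`generate_metabolite_panel()` applies DKD-vs-others log2 fold changes per
fluid on log-normal baseline concentrations (biological log-SD 0.4),
censors below the per-metabolite LOD (indoxyl sulfate 15.2 nmol/L,
p-cresyl sulfate 22.4 nmol/L — the validated platform limits), and adds
missingness completely at random (no missingness mechanism is stated
upstream). `generate_outcomes()` uses exponential event times within the
3-year horizon — the projection machinery upstream is
distribution-agnostic — with group hazards matching the projected 3-year
risks (0%, 7.8%, 34%), a 12.5 hazard ratio between the latent high/low
strata inside the T2DM group (the low-stratum hazard solved so the marginal
group risk is preserved), and a 0.02/year competing non-renal mortality
hazard, a typical figure for a diabetic cohort of this age.

`render_urine_series()` draws geometric phantoms, not photorealistic urine:
a 12-patch colour card, a liquid column at the cast-distorted CIELAB colour,
and a foam band following $h(t) = h_0 2^{-t/T_{1/2}}$ whose bubbles are
non-overlapping disks from a two-component log-normal mixture (micro
≈ 0.32 mm, macro ≈ 1.0 mm; disease shifts weight to the micro component).
Ground-truth masks and bubble tables are returned so extraction can be
scored. Bubble centres are continuous, so rasterisation error averages out
over bubbles; the suite bounds the total mask-vs-analytic area discrepancy
at 2%.

**Problem sizes.** The validation suite exercises the generators at the
sizes where each claim is sharp: 2000/group for marginal convergence (5%),
5000 for copula correlations (±0.04), 20 000 for Cox hazard-ratio recovery
([1.85, 2.15] for a true ratio of 2), 5000 for the Fine-Gray oracle, 500 × 10
seeds for the selection-leakage guard, and the study's own 80/102/100 for
the tier comparison. The acceptance script runs the full pipeline at the
study sizes with 10 × 5 cross-validation, 1000 permutations and 1000
Monte-Carlo iterations.

**Frame times.** The default imaging schedule is the protocol's
0/30/60/120 s. For half-life *recovery* experiments the tests use a denser
early schedule (0, 5, 15, 30, 60, 120 s): a healthy-range T₁/₂ of 4.2 s
leaves sub-pixel foam by the first 30 s frame, so the protocol schedule
cannot identify fast decays — a genuine limitation of four fixed late
frames, not of the estimator.

**What passing tests do not show.** The generator emulates marginals,
a low-rank correlation structure, MCAR missingness and exponential
hazards. Real cohorts have richer dependence (e.g. eGFR-UACR coupling,
medication effects), informative missingness, measurement drift, and images
with glare, menisci and non-disk bubbles. Passing this suite demonstrates
that the *computations* are correct and internally consistent under known
ground truth, not that the discriminative performance transfers to clinical
data.

## Numerical choices and degenerate inputs

* O-PLS deflation stops early if an orthogonal weight vector has norm
  < 1e-10 (no class-orthogonal variation left).
* `estimate_half_life()` with only the t = 0 height positive reports half
  the first inter-frame gap — the decay is below resolution, and the
  estimate is an upper bound of that order; with a non-negative fitted
  slope the half-life is infinite and flagged censored.
* DeLong comparison of a predictor with itself returns p = 1 directly
  (the variance of the difference is identically zero).
* Bootstrap resamples for NRI/IDI are redrawn until both classes are
  present, keeping the statistic defined.
* Constant features entering RFE are dropped first with a warning;
  constant predictions make the calibration slope undefined (warned, `NA`).
* All generators and resampling routines take explicit integer seeds;
  fold assignments derive from them, so every reported number is
  reproducible byte-for-byte.

## Known limitations

* The copula closes unspecified correlations with independence outside the
  physicalomics block; clinical covariates are therefore less collinear
  than in real cohorts, which flatters feature selection.
* MBI extraction relies on bubbles rendered as bright caps on a darker
  matrix; heavily merged real foam would need marker-controlled watershed
  beyond the distance-map seeding used here.
* The TUS definition is this package's (documented) formalisation of a
  named but undefined normalisation; analyses sensitive to it should run
  the concordance check.
* Apparent AUC uses training-set predictions of the full forest, which for
  random forests is nearly 1 by construction; it is reported for the
  optimism decomposition, not as a performance claim.
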