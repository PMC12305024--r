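---
title: "Methods: from irradiance spectra to adaptive optima"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from irradiance spectra to adaptive optima}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

photoniche asks a community-ecology question with comparative-methods
machinery: do species that occupy the same forest light microhabitat — for
example Müllerian comimics sharing a warning pattern — evolve toward shared
adaptive optima in sensory and flight-related traits? This vignette records
the models, the parameter choices, the numerical decisions, and what the
synthetic-data tests do and do not establish.

## 1. The visual model

Ambient irradiance `I(λ)` (W m⁻² nm⁻¹) is converted to quantal units by
`I_q(λ) = I(λ)·λ·10⁻⁹/(hc)` (CODATA `h`, `c`), then reduced to one quantum
catch per receptor class:

    Q_i = ∫ S_i(λ) I_q(λ) dλ,   λ ∈ [310, 670] nm

with spectral sensitivities `S_i` built from the Govardovskii et al. (2000)
A1 α-band template at the trichromatic nymphalid peak wavelengths
λmax = 340 (UV), 435 (B), 545 (LW) nm. The β-band is off by default and
switchable; the published template analyses do not state the β-band
treatment, so the choice is flagged rather than asserted. The template's
analytic peak sits within 1 nm of λmax (a known property of the rational
form); curves are renormalized so the grid maximum is exactly 1.

Achromatic *photon catch* is `Q_LW` (the invertebrate achromatic channel),
with the three-channel mean as an alternative; both are log10-transformed
before analysis. Spectral composition is summarized by Michelson relative
catches, e.g. `rel_UV = (Q_UV − M)/(Q_UV + M)` with `M = (Q_B + Q_LW)/2`,
bounded in [−1, 1] and invariant to global intensity.

**Quadrature.** The measured spectrum is linearly interpolated and the
template evaluated analytically on a common grid, integrated by trapezoid.
The default grid step is **0.05 nm**, not the 1 nm a field instrument
suggests: with a 1-nm product grid the trapezoid error on smooth spectra is
O(10⁻⁵) relative, while the package's oracle tests require agreement with a
0.01-nm Riemann sum to 10⁻⁶. At 0.05 nm the error is below 10⁻⁷ and the
cost is negligible. Saturated/negative raw readings are clipped to zero
with a warning; calibration is a per-wavelength multiplicative gain,
linearly interpolated, and must cover the spectrum's span.

## 2. Canopy openness

Hemispherical photographs are reduced with the standard gap-fraction
pipeline: blue channel (best sky/canopy contrast), Otsu threshold computed
over in-circle pixels only, then gap fractions on 7 zenith rings × 8
azimuth segments over the 0–70° cap, assuming an equidistant projection
(zenith ∝ radial distance; 90° at the circle edge — the usual model for
clip-on fisheye lenses). Openness is the ring-averaged gap fraction
combined across rings; by default rings are weighted by the solid angle
they subtend within the cap,

    w_r = (cos θ_lo − cos θ_hi) / (1 − cos 70°),

with equal-weight averaging available (`weighting = "mean"`). The upstream
field pipeline does not state its ring weighting, so both are offered and
validated against synthetic ground truth instead of against another
implementation. Otsu thresholding assumes a bimodal histogram; a
near-uniform image (all sky, all canopy) splits its sensor noise instead
and is a documented failure mode — constant images raise an error.

## 3. Wing morphometrics

Silhouettes are Otsu-segmented, the largest connected component kept, holes
filled. Area is pixel count × scale². "Major and minor wing axes" are
operationalized as the axes of the moment-equivalent ellipse (eigenvalues
of the pixel covariance, + 1/12 per-pixel correction), which is rotation-
invariant; a bounding-box variant is available since the original adapted
scripts are not restated anywhere. Wing loading is body mass / forewing
area (g mm⁻²). Damaged wings are excluded by a per-record flag, not
detected automatically.

## 4. Ecological axes

Individual records are averaged to species means (after any transforms —
order matters and is tested), then decomposed by **correlation-matrix PCA**
(z-scored variables): the inputs mix units (quanta s⁻¹ m⁻², %, m, mm²,
g mm⁻²), so covariance PCA would be dominated by the catch scales. The
original analysis does not state its scaling; correlation PCA is the
defensible default and is flagged as a choice. Components with eigenvalue
≥ 1 are retained. Signs are conventions: EC1 is oriented so canopy openness
loads positively (bright microhabitats = high EC1), EC2 so flight height
loads positively. The same machinery serves the visual-trait PCA, whose
first component is reported with per-trait loadings so the allometric
control's loading can be inspected.

## 5. Phylogenetic regression

`pgls_fit` is GLS with residual covariance σ²C, where `C_ij` is the shared
root-to-tip path fraction under Pagel's λ (fixed at 1 by default for
conservative comparisons; λ = 0 reproduces OLS exactly — a tested
invariant). `mixed_fit` generalizes to individual-level data:
`y = Xβ + Σ_u b_u + e`, each random term `b_u ~ N(0, σ²_u Z_u K_u Z_uᵀ)`
with an optional level correlation `K_u` (the phylogenetic `C` for species;
crossed intercepts for sex or transect replicate/day/time-of-day).
Variance components are estimated by ML or REML over log-variances
(L-BFGS-B, bound −20 to avoid boundary pathologies, three extra starts on
failure); fixed effects are profiled by GLS; inference is by ML
likelihood-ratio tests and AICc, with ΔAICc < 2 treated as model
equivalence. This replaces Bayesian MCMC estimation deliberately: the
inferential targets (variance structure, fixed-effect signs, model
ranking) are the same, the estimator is deterministic and testable, and
posterior summaries are not reproduced. With a single phylogenetic term,
one observation per species and no residual term (`residual = FALSE`), the
mixed model reproduces the PGLS ML log-likelihood — a tested equivalence.

`sma_fit` implements standardized major axis allometry: per-group slope
`sign(r)·sd(y)/sd(x)`, a common-slope likelihood-ratio test on
residual-vs-fitted score correlations (Warton et al. 2006;
χ² with g−1 df), then — given the common slope — Wald tests on group means
of residual scores `y − bx` (elevation/grade shifts) and fitted scores
`y + bx` (shifts along the axis), both with the common-slope variance
propagated. Operating characteristics are validated by simulation: with
equal slopes 0.75 and an elevation offset of 0.5 (2.5 residual SDs) the
elevation test reaches ≥ 90% power at ≤ 10% type-I error; the
shift-along-axis scenario displaces groups by 2.5 in x, chosen a priori to
produce the same 2.5-SD effect measured along the fitted axis, mirroring
the elevation scenario.

## 6. Trait-evolution models over regime maps

Discrete mimetic clusters are mapped onto the tree by stochastic character
mapping under an equal-rates Mk model (the simplest defensible choice for
three unordered states; ordered/all-rates-different variants are out of
scope). The ML rate comes from Felsenstein pruning; node states are drawn
by stochastic traceback from the pruning conditionals (flat root prior);
branch interiors by endpoint-conditioned path sampling — rejection
sampling capped at 10⁴ attempts, then exact uniformization, which
guarantees termination. Sampled node-state frequencies are tested against
up-down marginal posteriors (≤ 0.05 maximum deviation over 2,000 maps).

Five Gaussian trait models are fitted by ML:

| model | covariance | free parameters (k) |
|-------|------------|---------------------|
| BM1   | σ²·t_shared | 2 |
| BMM   | Σ_k σ²_k·(shared time in regime k) | 1 + #regimes |
| OU1   | σ²/(2α)·e^{−α d}(1 − e^{−2α t}) | 3 |
| OUM   | as OU1, regime-specific optima in the mean | 2 + #regimes |
| EB    | σ₀²·(e^{r t_shared} − 1)/r, r ≤ 0 | 3 |

For OU models the expected tip value integrates the painted optima along
each root-to-tip path: `E[y_i] = e^{−αT} y₀ + Σ_k θ_k W_ik` with per-segment
closed-form weights. The root state is fixed at the root-regime optimum by
default; a free root is available behind `root = "estimated"` (for OU1 on
an ultrametric tree it is unidentifiable — the root and optimum columns are
collinear — hence the default). Optima, root and σ² are profiled
analytically by GLS given the shape parameter; α is maximized over
[10⁻⁶, 50]/depth (scale-free bounds) by a 24-point log-spaced grid refined
with Brent search, `r` over [−10, 0]/depth, BMM rate ratios by BFGS on
logs. All five likelihoods are checked against dense multivariate-normal
oracles with independently assembled covariances on trees ≤ 6 tips, and
the α → 0 limit against BM.

`compare_over_maps` fits BMM and OUM on each of (by default) 500 sampled
maps, the regime-independent models once, and tabulates per-map AICc
(n = number of tips) plus the fraction of maps each model wins. AICc's
known tolerance for weak multipeak signal is quantified rather than
assumed: under BM truth the multipeak OU model must win ≤ 20% of
replicates, under strong multipeak truth ≥ 90%.

## 7. The synthetic world, and what green tests mean

The generator states one world and keeps it fixed: 45 species on a
unit-depth pure-birth tree; 8 mimicry rings aggregated into 3 mimetic
clusters painted polyphyletically (each cluster ≥ 2 independent origins);
a latent light-preference trait evolving under multipeak OU with
phylogenetic half-life 10% of tree depth and stationary SD 0.25
(σ² = 2α·0.25²), optima −1 (clearwing), −0.6 (confusa), +1 (tiger-stripe)
— confusa shares the shaded microhabitat but diverges in wing morphology,
which is encoded in cluster-specific wing optima instead; 785 individuals
with truncated-geometric per-species sample sizes (1–65, matching the
highly skewed field sampling), individual spectra drawn as gap/shade
archetype mixtures weighted by the species' light preference, and
species-level random intercepts drawn with phylogenetic covariance so the
mixed model's assumed structure is literally present. Spectral archetypes
are parametric Gaussian-bump emulations of the classic "forest shade"
(dim, green-peaked) and "small gap" (bright, broad) irradiance classes —
sufficient to induce the catch contrasts the analysis consumes, not a
radiative-transfer model. Fisheye fixtures threshold a smoothed Gaussian
field at the exact in-disc quantile; wing fixtures are rotated ellipses.
One master seed spawns fixed-offset child seeds; every generator is a pure
function of (config, seed), tested byte-identical.

A green end-to-end test therefore establishes that *when* microhabitat
segregation and multipeak selection are present at the stated strength,
the pipeline detects them (tiger-stripe highest on EC1; OUM winning ≥ 90%
of 500 maps) and recovers the optima ordering — not that any field dataset
has this structure, and not that the estimators are robust to features the
generator omits: cloud-cover noise in spectra, non-Gaussian measurement
error, regime-dependent α or σ², polymorphic species, or canopy images
with exposure gradients.

## 8. Known limitations

* Gaussian responses only; the binary/categorical phylogenetic models of
  the original abundance analyses are out of scope.
* No receptor-noise (ΔS) chromatic discriminability, von Kries adaptation,
  or radiance modelling; irradiance only.
* No multivariate OU, no OUMA/OUMV (regime-dependent α or σ²), no
  measurement-error models.
* Equal-rates Mk only for regime histories.
* Otsu binarization fails on unimodal (near-constant) fisheye images.
* The printed explained-variance figures of the motivating field analyses
  are not reproducible here by design (the raw field data are not
  required); all empirical claims in this package are about the synthetic
  world and are computed by the tests themselves.
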