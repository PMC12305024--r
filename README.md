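# photoniche

Do species that share a forest light microhabitat converge on the same
sensory and flight phenotypes? In Müllerian mimicry systems — for example
neotropical ithomiine butterflies, where distantly related species sharing
one warning pattern also share flight behaviour — the light environment a
species flies in may set the selective regime acting on its eyes, brain and
wings. `photoniche` implements the full analysis chain for that question,
for visual ecologists and comparative biologists:

1. **Visual model** — spectral irradiance `I(λ)` → quantal flux
   `I_q(λ) = I(λ) λ/(hc)` → receptor quantum catches
   `Q_i = ∫ S_i(λ) I_q(λ) dλ` over 310–670 nm, with Govardovskii A1
   templates at λmax = 340/435/545 nm (UV/B/LW); achromatic photon catch
   (`Q_LW`, log10) and Michelson relative catches
   `(Q_a − M)/(Q_a + M)`, `M = (Q_b + Q_c)/2`.
2. **Canopy openness** — hemispherical photographs → blue channel → Otsu
   threshold → gap fractions on 7 zenith rings × 8 azimuth segments
   (0–70°) → solid-angle-weighted openness (%).
3. **Wing morphometrics** — silhouette segmentation → area (mm²),
   moment-ellipse aspect ratio, wing loading (g mm⁻²).
4. **Ecological axes** — species means → correlation-matrix PCA →
   EC1 ("light environment", canopy openness loading positive) and EC2
   ("flight-related wing morphology"); the analogous visual-trait PCA.
5. **Phylogenetic statistics** — PGLS with Pagel's λ (default 1),
   Gaussian phylogenetic mixed models (ML/REML over correlated random
   effects), AICc comparison (ΔAICc < 2 ≡ equivalent), and SMA allometry
   with slope / elevation (grade) / major-axis shift tests.
6. **Trait-evolution models** — equal-rates Mk fitting and stochastic
   character mapping (SIMMAP) of mimetic-cluster regimes; BM1, BMM, OU1,
   multipeak OU (OUM, one adaptive optimum θ per regime, selection
   strength α, rate σ²) and early-burst (EB) likelihoods fitted by ML
   with analytic GLS profiling; AICc densities over ensembles of 500
   stochastic maps.
7. **Synthetic communities** — a fully deterministic generator (trees,
   polyphyletic regime paintings, OUM traits, gap/shade irradiance
   archetypes, fisheye and wing images, 785 individual records) with
   recorded ground truth, so every stage is testable without field data.

## Worked example

```r
library(photoniche)

# a bright "small gap" irradiance spectrum -> receptor catches
cs <- catch_set(archetype_spectrum("gap"))
cs
#> <catch_set> Q_UV=3.715e+19 Q_B=1.201e+20 Q_LW=2.271e+20  rel=(-0.647, -0.048, 0.486)
```

The gap archetype is long-wavelength rich: the LW channel catches
2.27×10²⁰ quanta s⁻¹ m⁻² and its Michelson relative catch is +0.49, while
the UV channel sits at −0.65 (UV-starved relative to the other channels).

```r
# a synthetic 45-species community with known multipeak-OU ground truth
com <- simulate_community(synthetic_config(seed = 1), images = FALSE)
com
#> <synthetic_community> 45 species, 785 individuals, 3 clusters
#>    clearwing      confusa tiger-stripe
#>           24           14            7

pipe <- run_pipeline(com, n_maps = 500, seed = 42)
round(pipe$pca$explained_pct[1:3], 2)
#> [1] 65.26 24.90  6.20
round(pipe$cluster_means, 2)
#>    clearwing      confusa tiger-stripe
#>        -1.45         0.40         4.18
pipe$ensemble
#> <map_ensemble> 500 maps (500 used, 0 fit failures)
#> fraction of maps won:
#>  BM1  BMM  OU1  OUM   EB
#> 0.00 0.01 0.00 0.99 0.00
```

EC1 (65.3% of variance) separates the gap-dwelling tiger-stripe cluster
(mean +4.18) from the shade-dwelling clearwing cluster (−1.45), and the
multipeak OU model — one adaptive optimum per mimetic cluster — wins on
99% of the 500 stochastic regime maps, exactly the structure the generator
encodes.

```r
# canopy openness from a synthetic hemispherical photo with known truth
f <- simulate_fisheye(0.4, seed = 7)
estimate_openness(f$image)$openness_pct
#> openness 40.9% (truth 40.9%)
```

Command-line wrappers live in `inst/cli/` (`spectra`, `canopy`, `wings`,
`axes`, `evofit`, `simulate`), e.g.

```sh
Rscript inst/cli/simulate.R --seed 1 --out community
Rscript inst/cli/evofit.R --tree community/tree.nwk --data ec1.csv \
  --trait EC1 --regimes mimetic_cluster --nmaps 500 --seed 42 --out aicc.csv
```

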