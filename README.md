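# rnlvision

Predator-vision analysis of animal coloration in R: from raw reflectance
spectra to just-noticeable-difference (JND) conspicuousness contrasts and
information-theoretic mixed-model inference.

The package is aimed at visual ecologists asking how conspicuous a prey
phenotype is *to a particular viewer* against *a particular background* —
here, red and green poison-frog dorsa viewed by a tetrachromatic UV-sensitive
bird, a tetrachromatic Anoline lizard (with oil-droplet-filtered cones) and a
dichromatic crab, against green leaves, leaf litter and tree trunks.

## The model

For receptor class *i* with spectral sensitivity *S<sub>i</sub>(λ)*, stimulus
reflectance *R(λ)* and illuminant *I(λ)*, the quantum catch is

    Q_i = Σ_λ R(λ) I(λ) S_i(λ) Δλ

Discriminability follows the receptor-noise-limited (RNL) model: receptor
noise is Weber-anchored, *e<sub>i</sub> = ω<sub>ref</sub> √(η<sub>ref</sub> /
η<sub>i</sub>)* with η the relative receptor densities, and the chromatic
distance between stimuli *a* and *b*, with Δf<sub>i</sub> = ln(Q<sub>i,a</sub>
/ Q<sub>i,b</sub>), is

    ΔS² = [ Σ_{i<j} (Π_{k∉{i,j}} e_k²) (Δf_i − Δf_j)² ] / [ Σ_i Π_{k≠i} e_k² ]

(the familiar Vorobyev–Osorio dichromat and tetrachromat formulas are the
n = 2 and n = 4 cases). The achromatic contrast is ΔL = |ln(Q<sub>L,a</sub> /
Q<sub>L,b</sub>)| / ω<sub>L</sub>, with the luminance channel a single avian
double cone (563 nm) or the summed long-wavelength receptors (lizard, crab).
Both are in JND: 1 JND is the threshold of discriminability.

Contrast tables are then analysed by AICc-based multi-model inference over
all 113 marginality-respecting linear mixed models in four predictors
(species, morph, substrate, predator) with a per-individual random intercept:
Akaike weights, evidence ratios, 95% confidence sets, per-term importance and
model-averaged coefficients with unconditional standard errors.

## Worked example

```r
library(rnlvision)

study <- generate_study(seed = 1)            # 288 frog + 162 substrate spectra
frogs <- average_replicates(preprocess_spectra(study$frogs),
                            c("individual", "species", "morph", "locality"))
subs  <- average_replicates(preprocess_spectra(study$substrates), "type")
tab   <- contrast_table(frogs, subs, study$illuminant, build_all_systems())

aggregate(deltaS ~ morph + predator, tab, mean)
#>   morph predator    deltaS
#> 1 green     bird  6.774867
#> 2   red     bird  9.809843
#> 3 green     crab  2.823207
#> 4   red     crab  5.441459
#> 5 green   lizard 12.262886
#> 6   red   lizard 17.163096
```

Red frogs are far more chromatically conspicuous to the tetrachromatic bird
(mean ΔS ≈ 9.8 JND) and lizard than to the dichromatic crab (≈ 5.4 JND);
green frogs sit closer to their backgrounds throughout. The model-averaged
effect table for this run:

```r
fit <- mmi(tab, "deltaS")
head(fit$averaged[, c("term", "n_models", "importance", "estimate", "strong")])
```

gives per-coefficient importance, the conditional model-averaged estimate,
and a strong-effect flag (95% CI excluding zero), mirroring the usual
"number of models / importance / CI / estimate" report format.

The whole pipeline (preprocess → contrasts → perceptual spaces → statistics,
with CSV outputs and a YAML manifest) is one call:

```r
run_pipeline(pipeline_config(simulate = TRUE, seed = 1, out_dir = "out"))
```

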