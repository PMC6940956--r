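# droughtlight

Tools for dissecting photosynthesis under drought stress in barley-type
cereals: JIP-test analysis of fast (OJIP) chlorophyll-*a* fluorescence
transients, negative-binomial differential-expression calling with FDR
control, GO-term enrichment, position-weight-matrix promoter scanning with
exact p-values, and designation of transcription-factor →
photosynthesis-gene regulatory pairs. Every stage has a synthetic
generator with recorded ground truth, so the whole chain runs and is
tested without instrument or sequencing data.

Intended users: plant phenomics and transcriptomics researchers who want a
transparent, fully testable re-implementation of this analysis chain, and
method developers who need planted-truth simulations for fluorescence and
expression estimators.

## The core quantities

From a dark-adapted fluorescence rise, the landmarks F₀ (50 µs), F₃₀₀
(300 µs), F_J (2 ms), F_I (30 ms) and F_M (trace maximum) yield

```
V_J = (F_J − F₀)/(F_M − F₀)          relative variable fluorescence at J
M₀  = 4·(F₃₀₀ − F₀)/(F_M − F₀)       initial rise slope
φP₀ = 1 − F₀/F_M                     max quantum yield of PSII photochemistry
ψE₀ = 1 − V_J,  φE₀ = φP₀·ψE₀,  δR₀ = (1 − V_I)/(1 − V_J)
ABS/RC = (M₀/V_J)/φP₀,  TR₀/RC = M₀/V_J,  ET₀/RC = (M₀/V_J)·ψE₀
PI_ABS = (φP₀·V_J/M₀) · φP₀/(1 − φP₀) · (1 − V_J)/V_J
```

ΔV_t curves (treated − control) localize stress signatures: a positive
K-band at 300 µs indicates donor-side (oxygen-evolving complex) damage.
Differential expression uses a per-gene NB Wald test (median-of-ratios
normalization, method-of-moments dispersion with a conservative
common-dispersion floor), DEGs at |log2FC| ≥ 2 and BH FDR ≤ 0.01;
enrichment is the exact hypergeometric test with Benjamini–Yekutieli
adjustment and a minimum of five mapped genes per term; promoter hits are
log-likelihood-ratio PWM scores with p-values computed exactly by
dynamic-programming convolution on a 1/1000-bit grid; qPCR fold change is
FC = E^(−ΔCt).

## Worked example

```r
library(droughtlight)

# a noisy stressed transient with known truth
sim <- simulate_ojip_transient(
  stress_preset(transient_spec(noise_sd = 0.01, seed = 7)))
lm <- extract_landmarks(sim$transient)
lm
#> JipLandmarks 'trace_prolonged_drought': F0=597.1 F300=1018 FJ=1430
#>   FI=1847 FM=2031 | VJ=0.5806 VI=0.8716 M0=1.1746
pp <- cross_section_fluxes(jip_parameters(lm), lm)
c(pp$phiP0, pp$PI_ABS, pp$ABS_RC)
#> [1] 0.706 0.605 2.865
```

The depressed F_M of the stress preset lowers φP₀ (healthy leaves sit near
0.8) and more than halves the performance index, while the apparent
antenna size per active reaction centre (ABS/RC) rises — the classic
prolonged-drought signature. The differential curve localizes the injected
donor-side damage:

```r
ctrl <- simulate_ojip_transient(transient_spec(noise_sd = 0, seed = 1))
strs <- simulate_ojip_transient(
  stress_preset(transient_spec(noise_sd = 0, seed = 2)))
d <- differential_curve(relative_variable_fluorescence(strs$transient),
                        relative_variable_fluorescence(ctrl$transient))
round(d$bands, 4)
#>     dK     dJ     dI
#> 0.0745 0.0480 0.0497
```

The K-band (0.0745 at 300 µs) dominates its neighbours, and its positive
sign follows the treated-minus-control convention. The packaged 17-pair
regulatory table summarizes to the published family and direction counts:

```r
summ <- summarize_pairs(read_pairs_table())
c(summ$total, summ$by_family[["bZIP"]], summ$by_direction[["up"]],
  summ$by_direction[["down"]])
#> [1] 17  6  8  9
```

`run_pipeline(pipeline_config(seed = 1))` executes the full synthetic
chain (simulate → jip → deg → enrich → scan → pairs) and writes
`jip_parameters.tsv`, `delta_vt.tsv`, `deg_table.tsv`, `enrichment.tsv`,
`hits.tsv`, `pairs.tsv` and a checksummed run report.

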