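---
title: "Methods: JIP-test fluorescence analysis and drought transcriptomics"
author: "droughtlight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: JIP-test fluorescence analysis and drought transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtlight)
```

# Scope

`droughtlight` packages the computational chain used to dissect
photosynthesis under drought stress in a cereal crop: fast chlorophyll-a
fluorescence (OJIP) transients reduced to JIP-test parameters, bulk
differential-expression calling with FDR control, GO-term enrichment,
promoter scanning with position weight matrices, and the designation of
transcription-factor-to-photosynthesis-gene regulatory pairs. Because raw
fluorimeter traces, microarray intensities and RNA-seq counts are rarely
redistributable, every stage is paired with a synthetic generator that
records its ground truth, so the whole chain is testable end to end.

# The OJIP transient model

A dark-adapted leaf exposed to saturating light shows a fast polyphasic
fluorescence rise with inflections at O (~50 µs), J (~2 ms), I (~30 ms) and
the peak P (the maximal fluorescence F~M~). The simulator is deliberately
phenomenological — a sum of three saturating exponentials, one per kinetic
phase, scaled between F~0~ and F~M~:

$$F(t) = F_0 + (F_M - F_0)\sum_{k \in \{OJ, JI, IP\}} a_k\,(1 - e^{-t/\tau_k})
  + k_{band}\,(F_M-F_0)\, e^{-\frac{(\ln t - \ln 3\cdot 10^{-4})^2}{2\sigma_K^2}}$$

with amplitudes $a_k \ge 0$ summing to one, strictly increasing time
constants, and an optional log-normal bump centred at 300 µs that emulates
the K-band deviation produced by an impaired oxygen-evolving complex.
Multiplicative Gaussian noise models detector noise. This is **not** a
kinetic electron-transport model (no Q~A~/Q~B~ ODEs); it reproduces the
shape features the downstream JIP algebra consumes — landmark intensities,
monotone rise, FM depression, I-P loss and a localized K-band — and nothing
deeper. Conclusions from passing tests therefore concern the estimators,
not photosynthetic biophysics.

Defaults: $F_0 = 500$, $F_M = 2500$ (typical instrument counts), amplitudes
$(0.5, 0.3, 0.2)$ and time constants $(0.4, 8, 80)$ ms chosen to put
V~J~ ≈ 0.57 and V~I~ ≈ 0.86, in the range seen in healthy cereal leaves.
The sampling grid is 120 log-spaced points over 10 µs–1 s, the schedule of
PocketPEA-class instruments; the four landmark times are snapped onto the
grid exactly, so landmark extraction on synthetic traces needs no
interpolation (real traces are interpolated linearly in $(\ln t, F)$, the
conventional log-time view of OJIP curves). The grid size is configurable
because instrument schedules vary. The K-band width is fixed at
$\sigma_K = 0.35$ ln-units (~0.15–0.6 ms), keeping the bump local to the K
step. The `"prolonged_drought"` preset scales F~M~ by 0.8, the I-P
amplitude by 0.6 (amplitudes are renormalized to keep their unit sum) and
sets $k_{band} = 0.05$; these are tuning constants that reproduce the
*direction* of drought signatures, not measured values.

# JIP-test parameters

Landmarks are read at fixed times: F~0~ at 50 µs, F~300~ at 300 µs, F~J~ at
2 ms, F~I~ at 30 ms; F~M~ is the global trace maximum rather than the last
sample, because P is defined as maximal fluorescence and stressed traces
can decline after the peak. The I-step time is taken as 30 ms from the
conventional phase boundary (the J-I phase ends and the I-P phase begins at
30 ms); instrument software may use a slightly different point, which is
why the landmark times are arguments, not constants, internally.

From $V_J$, $V_I$ and the initial slope $M_0 = 4(F_{300}-F_0)/(F_M-F_0)$
the standard quantum yields, per-reaction-centre fluxes, and the
performance index follow (see `?jip_parameters` for the full set). Two
numerical conventions matter:

* **Per-cross-section fluxes.** The framework defines ABS/CS, TR~0~/CS,
  ET~0~/CS and DI~0~/CS without a closed formula; we adopt the standard
  proxy ABS/CS~0~ ≈ F~0~ (switchable to F~M~), which makes
  $RC/CS_0 \cdot ABS/RC = F_0$ an exact internal identity consistent with
  the RC/CS~0~ formula.
* **Differential curves.** $\Delta V_t$ is treated-minus-control, the sign
  under which donor-side stress shows a *positive* K-band. Curves on
  different grids are interpolated onto a shared log-spaced grid over the
  overlapping time range.

All algebraic identities (yield complementarity, flux additivity, the
factored versus expanded performance index) are enforced by property tests
at 1e-12 relative tolerance over randomized valid landmark sets.

# Differential expression

RNA-seq-mode normalization uses median-of-ratios size factors (geometric
mean reference over genes with all-positive counts). Microarray-mode
intensities get a per-chip 75th-percentile shift to zero followed by
per-gene median centring.

The two-group test is a transparent per-gene negative-binomial Wald test,
implemented directly rather than delegated, so that its behaviour on
planted-truth simulations is fully inspectable: log2 fold change
$\log_2\frac{\bar{x}_B + 0.5}{\bar{x}_A + 0.5}$ (the 0.5 pseudo-count keeps
zero-mean genes finite), delta-method standard error under the NB variance
$\mu + \alpha\mu^2$, and a two-sided normal reference. The gene-wise
dispersion $\hat\alpha$ comes from the method of moments on within-group
means and variances. With three replicates per group the raw gene-wise
estimate is very noisy, and understated dispersions inflate the Wald
statistic; we therefore floor $\hat\alpha$ from below at the dataset-wide
median of the gene-wise estimates. This is a conservative floor, not
empirical-Bayes shrinkage: estimates above the floor are untouched. At the
package's reference simulation scale (2000 genes, 3 vs 3, dispersion 0.05)
this calibrates the null — about 5% of null genes fall below p = 0.05 and
essentially none survive BH FDR ≤ 0.01 — while a heavier-tailed t reference
would have destroyed all power at FDR 0.01 (with 2000 tests the smallest
BH-adjusted t~4~ p-value is near 1).

DEGs are called at the inclusive thresholds |log2FC| ≥ 2 and BH FDR ≤ 0.01.
One known boundary effect is worth stating plainly: when the simulated
effect size sits exactly at the fold-change threshold (planted |log2FC| =
2), the estimate is symmetrically distributed around the boundary, so only
about half of the planted genes clear the estimated-fold-change filter no
matter how well the test is calibrated — the FDR gate alone recovers ~95%
of them. Detecting boundary effects of this kind is precisely what the
generator's recorded truth is for; recovering ≥90% of planted genes
through the combined filter requires planting effects comfortably above
the threshold (|log2FC| ≳ 2.4 at these settings).

Top-variance clustering ranks genes by cross-sample standard deviation
(ties broken lexicographically by gene id, zero-variance genes excluded),
z-scores each gene and runs either k-means (fixed seed, 10 restarts) or
average-linkage hierarchical clustering on 1 − Pearson distance.

# Enrichment

GO enrichment is the one-sided (over-representation) hypergeometric test
per term, restricted to terms with at least five background mappings, with
Benjamini–Yekutieli adjustment across terms by default — the harmonic-sum
penalty buys FDR control under the strong dependence between nested GO
terms. The p-values are exact (verified against brute-force combinatorial
enumeration on all backgrounds up to N = 30), so the only approximation in
the enrichment stage is the annotation itself.

# Promoter scanning and regulatory pairs

Motifs are probability matrices (MEME minimal format) with an additive
pseudocount of 1e-4 per cell, renormalized, so degenerate columns keep the
log-likelihood ratio finite. A window of length $L$ scores
$\sum_i \log_2(p_{i,w_i}/b_{w_i})$ bits against the background $b$; both
strands are scanned and windows containing N are skipped.

P-values are exact under the background model: per-position scores are
rounded to a 1/1000-bit grid and their distributions convolved by dynamic
programming, giving the full null tail in $O(L \cdot \text{range})$
integer-grid operations. The discretization bound is the only error
source; at 1/1000 bit it is far below displayed precision, and the DP tail
is verified against exhaustive $4^L$ enumeration for every packaged motif.
Reported hits satisfy p ≤ threshold (default 1e-4 — note a motif of length
$L$ cannot beat $4^{-L}$ under a uniform background, so 6-mers need a
looser threshold); per motif, BH q-values are computed over all scored
windows, and overlapping hits of one motif on one promoter keep only the
best-p site, so each site is counted once. Coordinates are 0-based on the
supplied promoter's plus strand.

Pair designation is a deliberate cross-reference, not an inference: a
(TF gene, target gene) pair requires the TF to be differentially
expressed, the motif to be explicitly assigned to that TF in a supplied
two-column table (no orthology projection is attempted), and at least one
surviving hit in the target's promoter. The promoter window defaults to
1500 bp upstream in the generator and is configurable, since upstream
window conventions vary. Pairs are sorted by TF fold change ascending, and
summaries count pairs by TF family and by TF direction.

# Group statistics

One-way ANOVA (per time point; the factorial genotype-by-condition layout
is out of scope) is followed by Tukey's HSD on the studentized-range
distribution. Compact letters are assigned one letter per maximal clique
of the non-significant-difference graph (Bron–Kerbosch on the handful of
groups a panel ever has), so two groups share a letter exactly when their
Tukey-adjusted p exceeds alpha; letters are ordered by descending group
mean. Correlations are reported as signed R², i.e. $\mathrm{sign}(r)\,r^2$,
the convention under which tight negative associations print as negative
values. qPCR fold change is $FC = E^{-\Delta C_t}$ with the gene's mean
amplification efficiency $E \in (1, 2]$; reference-gene pre-subtraction
(ΔΔCt style) is available but off by default because the bare formula does
not include it. Dehydration water loss is $WL = D_w \cdot 100 / F_w$ with
the stop flag at 70% remaining weight.

# Orchestration and determinism

`run_pipeline()` executes simulate → jip → deg → enrich → scan → pairs
from one YAML-backed configuration in which every threshold is an explicit
named key (lfc = 2, fdr = 0.01, enrichment alpha = 0.05, min mapping = 5,
scan p ≤ 1e-4). Every simulator takes an explicit seed and uses a private
RNG stream restored afterwards — no hidden global state — so a fixed
configuration reproduces byte-identical outputs; the run report carries
md5 checksums, parameter echo and stage counts. The exported functions and
this configuration surface are the package's interface; a thin
command-line wrapper over `run_pipeline()` ships in `inst/scripts/`.

# Problem sizes and limitations

The test and acceptance suites run at desk scale, chosen to finish in
minutes while keeping estimates stable: 10,000 random landmark sets for
the algebraic identities, 50 noisy traces for landmark recovery,
2000-gene 3-vs-3 count simulations for DE calibration and power,
exhaustive enumeration for motifs up to length 8, and backgrounds up to
N = 30 for enrichment exactness. What the synthetic data cannot show:
real OJIP traces carry instrument artefacts (gain switching, early-time
distortion) absent from the model; real counts have correlated genes,
batch effects and composition biases that the independent-gene NB
generator omits; and real promoter scans inherit whatever ascertainment
the motif collection carries. Headline biological numbers that depend on
the original raw data and database versions (genome-wide DEG totals, the
15119-site promoter tally) are out of reach by construction; the package
reproduces the self-contained published quantities (the 17-pair table and
the TF-share arithmetic) and the methods' internal guarantees.
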