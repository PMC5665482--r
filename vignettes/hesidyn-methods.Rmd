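---
title: "Methods: the delayed Hes-ID-proneural circuit and its single-cell validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the delayed Hes-ID-proneural circuit and its single-cell validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hesidyn)
```

## The model and its assumptions

`hesidyn` models the core gene-regulatory circuit of neural stem cell (NSC)
fate: Notch input `I` activates transcription of a Hes-type repressor, Hes
protein homodimers repress the Hes promoter itself (with a transcriptional
delay) and the downstream proneural gene, and a pool of ID proteins
sequesters both Hes and proneural monomers into heterodimers. The full
equations are listed in the README; the assumptions that shape them are:

* **Lewis-style reduction.** One mRNA and one protein species per gene, no
  explicit nucleus/cytoplasm compartments. All of the maturation biology is
  compressed into one delayed argument: the homodimer concentration
  `t_i = 19` min in the past gates Hes transcription. With only this delay,
  sustained oscillation needs high cooperativity (`n = 5`); a longer delay
  tolerates less (`t_i = 25`, `n = 4` behaves equivalently, and the package
  asserts this).
* **Irreversible mass-action dimerization.** Hes-Hes, Hes-ID,
  proneural-proneural and proneural-ID pairing all share one forward rate
  `k`, with no dissociation: "high affinity" in its simplest form.
  Homodimerization consumes two monomers (`2 k p^2` in the monomer balance,
  `k p^2` in the dimer balance), so in the absence of synthesis and decay
  the quantity `p + 2 p2 + pid` is conserved — a property the tests check
  exactly.
* **Constant ID pool.** `ID` is a parameter, not a species: heterodimer
  formation does not deplete it. This matches the regime where ID
  expression is set on slower timescales than the Hes oscillation. Dynamic
  ID expression is out of scope.
* **Asymmetric repression.** Only the homodimer represses the Hes promoter
  (N-box logic), while the proneural promoter sees the pooled repressor
  `p2 + eps * pid` with `eps = 0.5`: the heterodimer is half as effective,
  so twice as much of it is needed for the same repression. This asymmetry
  is the mechanistic heart of the model — IDs *relieve* auto-repression
  (raising and stabilising Hes) while *retaining* proneural repression.
* **Shared Hill scale.** Every Hill term uses the same `h0` and `n`,
  including the Notch input term `H+(I)`. Notch and repressor
  concentrations are therefore on one molecule scale.
* **One degradation rate per protein arm.** Monomer, homodimer and
  heterodimer share `g_p` (Hes) or `g_a` (proneural); rates derive from
  half-lives as `g = log(2)/t_half`. The mRNA/protein half-lives of 24 and
  22 min are experimentally anchored; the proneural arm uses a single
  24 min half-life for all four species, the minimal symmetric choice since
  no separate values are established.

"Proneural activity", the quantity that decides fate, is the temporal mean
of the homodimer `a2` — the DNA-binding-competent form — not the mRNA. The
phase-diagram tibbles carry both (`mean_proneural`, `mean_proneural_mrna`)
because the two answer different questions: expression maps resemble the
mRNA readout, fate is driven by activity.

## Parameter values and calibration

Printed, experimentally anchored values: `m0 = 200` mRNA/min (the upper
limit implied by a 2^12 reads-per-million Hes ceiling and ~0.5e6 mRNAs per
cell, i.e. ~2000 = 2^11 Hes transcripts), half-lives 24/22 min,
`t_i = 19` min, `n = 5`, `eps = 0.5`. The remaining constants are not
experimentally determined; following the same logic used for the original
model — choose the translation rate so that protein levels are biological
and the oscillation sits in the 2-3 h ultradian band — we calibrated them
once, before any acceptance checks were written, by scanning
`p0 in [0.01, 5]`, `k in [1e-3, 0.1]`, `h0 in {100, 200, 500}` and fixing

* `p0 = pa0 = 0.05` protein per mRNA per minute,
* `k = 0.001` per molecule per minute,
* `h0 = 200` molecules,
* `ma0 = 200` mRNA/min (mirroring `m0`).

This set yields a 140 min Hes mRNA period at `I = 500` with mRNA swinging
roughly 190-1400 copies (mean ~630, an effective transcription rate of a
couple dozen mRNA/min), protein in the tens-to-hundreds range, oscillation
over a broad band of Notch input with an activation threshold near
`I ~ 150`, and all of the qualitative regime structure described below.
The calibrated values were frozen and are the package defaults
(`circuit_params()`, mirrored in `inst/extdata/circuit_defaults.yaml`).

Tunable analysis parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `rel_amp_tol` | 0.05 | peak-to-trough over mean below which a series counts as sustained; the regime boundary is sharp, so results are insensitive to this within a decade |
| peak prominence | 1% of range | ignores integrator ripple |
| peak separation | 10 min | well below any credible period |
| `theta_q`, `theta_d` | 0.05, 0.5 | fate-band edges as fractions of the unrepressed proneural activity (`reference_activity()`: `I = 0`, `ID = 0`); the underlying activity surface is stored per cell, so other cuts can be re-applied without re-simulating |
| `expressed_threshold` | 1 | log2(RPM+1) scale; ~1 RPM, the conventional single-cell detection floor |
| panel score | `log2(1 + sum RPM)` | pooling on the RPM scale keeps single-gene panels identical to the plain log transform; a per-gene-log mean is available via `method = "mean_log"` |

## Numerical scheme

The integrator is fixed-step classical Runge-Kutta (RK4) with the method of
steps: the delayed argument `p2(t - t_i)` is read from the stored solution
grid through Catmull-Rom cubic interpolation (finite-difference tangents;
exact on linear data), with constant history equal to the initial state for
`t < 0`. Defaults: `dt = 0.05` min (380 steps per delay at `t_i = 19`),
`t_end = 4000` min with a 2000 min transient discarded — over 14 cycles of
the 140 min rhythm for envelope and period estimates. Choices worth noting:

* `dt` must satisfy `dt <= t_i/10` unless `t_i < dt`, in which case the
  engine degenerates (by design) to a plain ODE step using the
  instantaneous homodimer — that limit is cross-checked against an
  independent adaptive integrator (deSolve's lsoda) to 1e-6 relative
  tolerance in the tests.
* Step-halving moves post-transient trajectories by far less than 0.1%
  (asserted), so the reported 140 min period is not a discretisation
  artefact; period estimates are grid-quantised only at the `dt` level.
* Negative excursions beyond -1e-9 abort with the failure time; smaller
  ones are clipped to zero. This separates round-off from genuine model or
  usage errors.
* Runs are bit-deterministic given parameters and grid.

Oscillation calls: a series is oscillatory when it has at least three
detected peaks *and* relative amplitude above `rel_amp_tol`; the period is
the median inter-peak interval, robust to a stray peak at the regime
boundary.

## What the sweeps show

`notch_dose_response()` and `sweep_2d()` reproduce the circuit's regime
structure: (i) Notch alone cannot silence the proneural gene — its mean
saturates at an intermediate plateau because every oscillation trough of
the repressor lets transcription recover; (ii) the Hes production rate
barely moves proneural output on the fate scale; (iii) a 5% relief of
auto-repression (`f = 0.05`) abolishes oscillations, sustains Hes high and
pushes proneural activity into the quiescent band; (iv) Notch and ID
jointly form the three-way switch — Diff at low-Notch/low-ID, aNSC at
high-Notch/low-ID, qNSC wherever ID is high. At `I = 0` quiescence is
carried solely by ID sequestration of proneural monomers, which requires
`ID` on the order of 3000-4000 molecules under the default constants;
hence the default fate-map axes `I in [0, 1000]`, `ID in [0, 4000]`.
Default phase-diagram resolution is 40x40 (1600 integrations, about two
minutes on one core).

## The synthetic single-cell generator

The generator replaces the published adult SVZ and embryonic VZ datasets
with matrices whose ground truth is known, so the whole classification
pipeline is testable end to end. It emulates: the subpopulation structure
(Id3+Hes+ 50, Id3+Hes- 10, Id3-Hes+ 25 NSCs plus 27 TAPs by default;
radial glia vs intermediate progenitors for the embryonic design), the
marker-panel contrasts between them (NSC markers high in NSCs, active/
progenitor markers and Delta ligands high in active cells and TAPs, Id4
co-varying with Hes only in the embryonic design), expression magnitudes
on the log2(RPM+1) scale (expressed panels at mean 6, sd 1; silent at
0.3, sd 0.3; 200 background genes at mean 1), and technical dropout.

Dropout is expression-dependent zero inflation,
`P(drop) = dropout^(mean/2)` with `dropout = 0.1`: near-silent genes are
exact zeros about 70% of the time (the dominant feature of real RPM
matrices), genes at the detection floor drop at roughly the nominal rate,
and strong markers are essentially never lost. Under these defaults the
classifier recovers the designed counts exactly at zero noise and within
±2 cells per subpopulation at default noise — the calibration the design
aims for, with misclassification dominated by rare silent-panel false
positives under the sum-RPM score.

What the generator does **not** emulate — and therefore what passing tests
cannot certify about real data: count-level sampling noise (no
negative-binomial layer; no statistics computed here need one), library-
size variation and batch effects, doublets, continuous differentiation
trajectories between subpopulations, and any correlation structure among
background genes. Results on real matrices depend additionally on
normalisation and annotation quality, which the pipeline takes as given.

## Degenerate inputs and tie-breaks

Constant series report `env_max = env_min = mean` and are non-oscillatory;
empty designs produce empty matrices and annotations; a 1x1 sweep equals
the direct `simulate + summarize` calls; PCA drops zero-variance genes,
fixes each component's sign by making its dominant loading positive, and
refuses fewer cells than components; panel matching is case-insensitive
with a synonym map (Tbr2 = Eomes), warns about unmatched genes and errors
only when a panel matches nothing; cells annotated TAP keep that label
regardless of scores; fate thresholds must satisfy `theta_q < theta_d`.

## Known limitations

* The fate thresholds and the oscillatory-amplitude tolerance are
  conventions, not measurements; conclusions should be read from the
  stored continuous summaries wherever they matter.
* The calibrated constants (`p0`, `k`, `h0`, `ma0`) are one point in a
  broad viable set; quantities tied to them (absolute protein copy
  numbers, the ID scale needed for quiescence at `I = 0`) are
  order-of-magnitude statements only. The oscillation period, by contrast,
  is set mainly by the delay and half-lives and is robust across that set.
* Period detection is peak-based; strongly relaxational or noisy signals
  with secondary shoulders would need the prominence threshold revisited.
* The single-cell module classifies by thresholding two panel scores; it
  is deliberately not a clustering method, and it inherits the marker
  panels' validity.
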