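---
title: "patchmorph: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{patchmorph: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
knobs matter, what the synthetic-data module does and does not emulate,
and where genuinely open design questions were settled. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The measurement model

All internal quantities live in a single unit system — mV, pA, ms — so
that a voltage/current slope is directly a resistance in GΩ (rescaled
once, to MΩ, at reporting) and τ/R is directly a capacitance in nF
(reported in pF). Unit handling therefore happens at the I/O boundary
only, never inside formulas.

**Passive properties.** The resting potential is the arithmetic mean of a
one-minute 0-pA trace; input resistance is the ordinary-least-squares
slope of steady-state voltage deflection against injected current over
the −100…0 pA sweeps of the 500-ms family (sweeps containing spikes are
excluded with a warning — the fit is defined on subthreshold responses);
the membrane time constant comes from a mono-exponential fit
$V(t) = V_{ss} + \Delta V\, e^{-t/\tau_m}$ to the onset transient of the
−40 pA sweep; capacitance is derived as $C_m = \tau_m / R_{in}$, so
$C_m R_{in} = \tau_m$ holds exactly by construction and is asserted in
the tests. The protocol description mentions a "−40 mV" hyperpolarizing
step; since the stimulus set contains only current steps, this is read as
the −40 **pA** step (a units slip), and the sweep choice is configurable
(`feature_config(tau_sweep_pA = ...)`).

**Sag.** The sag sweep is the hyperpolarizing 500-ms sweep whose
steady-state deflection is closest to −7.5 mV (ties break toward the
smaller-magnitude current, the conservative choice). The ratio
$(V_{ss} - V_{min})/(V_{min} - V_{rmp})$ is negative for a rebounding
hyperpolarization as literally written; published sag values are positive
percentages, so the magnitude ×100 is reported. The formula is invariant
under joint translation of trace and RMP, which the tests assert.

**Action potentials.** Spikes are upward crossings of 0 mV with a 1-ms
refractory merge. The AP threshold is the first sample of the upstroke
whose centered first-difference derivative exceeds 10 mV/ms; no smoothing
is applied by default (acquisition already includes a 2.9-kHz Bessel
filter; the derivative estimator is configurable in principle but the
centered difference at 20–50 kHz resolves the criterion well). Waveform
features are measured on the peak-aligned average of the first five
spikes at rheobase + 10 pA; because a 50-ms step near rheobase rarely
yields five spikes, repetitions of the same stimulus are pooled into one
event pool (the bundle carries them as `waveform_steps`). Amplitude, AHP
and AHP time-to-peak are measured relative to threshold; half-width is
the interpolated time between the two crossings of threshold +
amplitude/2.

Two conventions deserve a note. First, the AHP is defined here relative
to threshold (≈ −8 mV); comparison tables in the literature often print
the absolute trough voltage (≈ −47 mV) while describing the
threshold-relative definition — both carry the same information given the
threshold row. Second, the AHP trough is located as the **first local
minimum** after the peak rather than the window minimum: after the step
ends, the membrane legitimately decays toward rest, which lies far below
any AHP, so a window minimum would report the decay tail. A
window-edge-only minimum means the repolarization never turned around and
the AHP is reported missing.

**Firing.** The firing-rate curve is spikes per 0.5 s per depolarizing
500-ms sweep. The I-F slope is the linear coefficient *b* of a quadratic
least-squares fit restricted to suprathreshold sweeps — including the
flat silent range below rheobase would bias *b* downward — rescaled to
Hz/100 pA (the table-header unit; an occurrence of "pA/100 Hz" in running
text is treated as a typo since the printed values match the table). ISI
statistics come from the lowest-amplitude sweep with ≥ 10 spikes; with
exactly 10 spikes the "ninth" and the "last" ISI coincide, reconciling
the two phrasings found for the adaptation ratio.

## 2. Morphometry

Reconstructions are standard 7-column SWC; validation reports duplicate
ids, orphan/forward-referencing parents and wrong column counts with line
numbers. Arbors (basal = type 3, apical = type 4) are analyzed
separately, mirroring the published tables; a whole-arbor mode exists.
The edge connecting a stem to its soma parent belongs to the stem
segment, so segment lengths sum exactly to the arbor total.

Centrifugal ordering assigns order 1 to segments leaving the soma and
increments at every branch point tipward. The complexity index
`(Σ terminal orders + #terminals) × (total length / #primaries)` is
homogeneous of degree one in length (doubling coordinates doubles it) and
invariant under node subdivision — both are tested. Non-binary branch
points are allowed; the identity `ends − nodes = primaries` is asserted
only for strictly bifurcating arbors.

Sholl analysis uses exact segment–sphere geometry: for each straight edge
the squared distance to the center is quadratic in the arc parameter, so
ring crossings are quadratic roots in (0, 1] (re-entrant dendrites count
once per crossing) and shell lengths are exact arc-length partitions —
shell lengths sum to the total arbor length to machine precision, which
doubles as the conservation oracle. Spheres are 3D by default, centered
on the soma root node; a 2D (x–y projection) mode is provided because
tracing software offers both conventions and the original choice is not
stated. A dense-resampling oracle (0.02-µm steps) confirms intersections
exactly and shell lengths to 0.1%.

Soma area uses the shoelace formula on the traced contour polygon when
present, else πr² of the root soma radius, with provenance flagged.

## 3. The synthetic-data module

`simulate_cell()` integrates a leaky integrate-and-fire membrane (Euler,
compiled; the integrator refuses dt > τ/5) with three additions that the
feature set needs:

- a **stylized spike template** — piecewise-linear upstroke to threshold +
  amplitude and downstroke to threshold + AHP at specified dv/dt slopes,
  followed by a brief 3-ms recovery limb so the AHP trough is an interior
  minimum — giving waveform features analytic ground truth up to sampling
  quantization;
- **spike-triggered adaptation** (increment `adapt_increment_pA`, decay
  `adapt_tau_ms`), which produces ISI accumulation and a sublinear f-I
  curve; with the increment at 0 the adaptation ratio is 1, and the ratio
  decreases strictly with the increment (tested over five levels);
- an **H-like sag current** `g_h s (E_h − V)` with a sigmoidal
  hyperpolarization-activated gate, producing a genuine sag whose
  measured percentage responds monotonically to `g_h`.

Defaults describe a regular-spiking pyramidal cell consistent with the
recorded populations: leak reversal −77 mV, R = 150 MΩ, C = 150 pF
(τ ≈ 22 ms), threshold −40 mV, amplitude 58 mV, AHP −8 mV, dv/dt
+430/−60 mV/ms, adaptation 50 pA / 120 ms (chosen once so that the
emergent I-F slope ≈ 13 Hz/100 pA and mean ISI ≈ 50 ms match the
recorded cells), recording noise 0.3 mV SD. Noise is added to the
*recorded* trace, not the dynamics, so latent ground truth stays exact.

With a nonzero sag conductance the measured RMP sits above the leak
reversal and the measured input resistance below the membrane resistance
— that is correct physiology (the H-current depolarizes rest and shunts
the steady-state I/V slope), and it is why cohort targeting of RMP and
R<sub>in</sub> uses sag-free cells by default.

`generate_tree()` grows arbors by stochastic centrifugal branching
(segment lengths normal-truncated, bifurcation probability per segment
end, order capped) and records total length, node/end counts and
terminal orders *as grown*; the cross-check that `arbor_summary()`
reproduces this bookkeeping exactly is the generator's defining test.

`generate_cohort()` targets published group rows at the **latent
parameter level** — leak reversal for RMP, membrane resistance for
R<sub>in</sub>, capacitance via C = τ/R for τ<sub>m</sub>, with
SD = SEM·√n since only means, SEMs and n are printed — then simulates
full recordings and runs the real extraction over them, so cohort-level
results exercise the entire pipeline rather than painting features onto a
table. Draws below feasibility floors (20 MΩ, 5 ms) are resampled by
truncation and logged. For large statistical calibration runs
(thousands of seeds) a `simulate = FALSE` mode returns the latent draws
directly; extraction adds only sub-percent measurement error, so the
calibration conclusions are unaffected while the cost drops a
thousandfold.

**What a green test does and does not establish.** The generator draws
independent normal features per cell; real cells have correlated
features (R<sub>in</sub> and τ<sub>m</sub> share membrane area),
non-normal tails, electrode drift, and morphology correlated with
physiology — none of which is emulated. Green cohort tests therefore
establish that the *pipeline* recovers what the generator put in and that
the *statistics* behave as advertised under the stated normal model; they
do not validate the biological claims of any particular dataset.

## 4. Statistics

The group tables use the classical pooled-variance two-tailed Student's
t-test; recomputing published p-values from their printed mean/SEM/n
confirms the pooled form (a Welch option exists, off by default).
`ttest_from_summary(summarize(raw))` equals `ttest_two_sample(raw)`
exactly — an identity the tests assert to 1e-12, and the reason summary
statistics printed in a paper suffice to audit its table p-values.

Two-way ANOVA is backed by `stats::aov` behind the module's interface:
sequential sums of squares for the plain two-factor layout, and for
repeated measures the classical univariate mixed partition
(`Error(subject/level)`): the between factor is tested against
subjects-within-groups, the within factor and interaction against the
subject×level stratum. No sphericity correction is applied by default (a
Greenhouse–Geisser option is provided). A hand-partitioned 2×3 design
and an SS-conservation property over random layouts serve as oracles.
All-constant responses conventionally report F = 0, p = 1. Sidak
adjustment is the closed form 1 − (1 − p)^m, monotone and bounded by
Bonferroni.

## 5. Numerical choices

- **τ fit.** Full nonlinear iteration (`nls`) fails sporadically on both
  zero-residual (noiseless) and noisy scaled traces. Since the model is
  linear in $(V_{ss}, \Delta V)$ for fixed τ, the package minimizes the
  profiled residual sum of squares over τ with a 1-D `optimize` — exact
  on clean data, deterministic, and convergence-free. The fit window runs
  from step onset to five initial-τ estimates (capped at step end), the
  initial estimate being the (1 − 1/e) crossing time.
- **Sag trough.** The raw minimum of a noisy trace is an extreme-value
  statistic biased downward by the noise floor, so the trace is smoothed
  with a 10-ms running mean before the trough search (`sag_smooth_ms`,
  set 0 for the literal minimum). The sag trough develops on the
  H-current time scale (tens of ms), so the smoothing does not distort
  it; a residual noise floor of a few percentage points remains on
  near-zero-sag cells.
- **Steady-state window**: last 10% of the step (50 ms of 500 ms),
  configurable; not stated in the source protocols.
- **Rest-trace stability**: operationalized as |mean of first 10 s −
  mean of last 10 s| ≤ 2 mV, configurable; no quantitative criterion is
  published.
- **Serialization**: voltages are written with 17 significant digits in
  both native dialects, making write→read round trips bit-exact. The
  run-config format is JSON rather than TOML/YAML because no TOML/YAML
  parser is available in the supported dependency set.
- **HDF5**: the environment provides no R HDF5 binding, so the native
  bundle dialects are CSV (directory) and JSON; `bundle-h5`, `abf` and
  `nwb` are optional adapters that raise an informative error naming the
  missing dependency.

## 6. Reproducing printed tables, and its limits

`reproduce_tables()` applies the summary-statistics t-test to every row
of the four published comparison tables. Rows whose summaries are printed
with generous precision reproduce to ±0.002; rows whose SEMs are printed
with two decimals on values of order one (half-width, adaptation ratio,
AHP time-to-peak) cannot — the printed rounding itself moves p by more
than that. Three rows additionally disagree beyond rounding (one sag row,
one RMP row, one basal-count row), and one apical-complexity entry is
typographically garbled in the source; these are excluded from the
acceptance targets, which use eight rows verified to reproduce within
±0.002.

## 7. Statistical power and the effect-direction check

The acceptance suite requires synthetic cohorts parameterized from the
prelimbic-L2/3 RMP, R<sub>in</sub> and τ<sub>m</sub> rows to recover the
published effect direction in ≥ 80% of seeds. At the printed effect
sizes and sample sizes, the per-row replication power is only ~50–60%
(two-sided α = 0.05; printed p-values of 0.03–0.04 imply roughly
coin-flip replication). The criterion is therefore operationalized at
the **cohort level**: a seed counts as detected when at least one of the
three targeted features is significant with the published SNI-vs-sham
sign and none is significant with the opposite sign (analytically ≈ 0.9
under independence). Per-row rates are also printed by the test for
transparency. Reading the criterion row-wise would leave it
unattainable by the stated world — not by the implementation.

## 8. Known limitations

- The LIF template makes dv/dt extrema and half-width quantized by the
  sampling grid (e.g. a 430 mV/ms upstroke renders as 387 mV/ms at
  20 kHz); recovery tests of waveform features use constructed waveforms
  where exactness is required.
- No multi-exponential or compartmental fitting; pipette/access artifacts
  are metadata, not modeled.
- Morphology generation is geometric, not biophysical: no tropism, no
  spine statistics, no shrinkage correction, no soma reconstruction
  beyond a contour polygon.
- ABF/NWB ingestion requires optional readers not present in the
  supported environment; the documented CSV/JSON bundle layouts are the
  interchange formats.
- The repeated-measures ANOVA assumes complete subject×level tables and
  reports the uncorrected univariate tests by default, matching the
  analysis style it reproduces.
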