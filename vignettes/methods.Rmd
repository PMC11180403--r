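---
title: "Models and methods behind hpitrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hpitrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpitrial)
```

`hpitrial` reconstructs, end to end, the computational machinery of a
randomized trial comparing predictive-alarm-guided with reactive
management of intraoperative hypotension. This vignette documents the
models, the parameters that matter, the numerical conventions, and the
design choices made where published descriptions of such trials leave the
details open.

## The burden metrics

All severity endpoints derive from one definition. With MAP sampled every
`cadence_s` seconds (default 20 s, the update rate of waveform-derived
monitor parameters) and a threshold $\theta$:

$$\mathrm{AUC}_{<\theta} = \sum_k \max(0,\ \theta - \mathrm{MAP}_k)\,\Delta t,
\qquad
\mathrm{TWA}_{<\theta} = \frac{\mathrm{AUC}_{<\theta}}{\text{total surgical duration}},$$

with $\Delta t$ in minutes. Numerical conventions, each isolated behind a
single routine so alternatives are one-line changes:

* **Rectangle rule, no interpolation.** Each sample represents its
  following interval; no crossing times are interpolated. This matches the
  discrete update semantics of the monitor and makes results
  bit-reproducible.
* **Strict inequality at the threshold.** A sample exactly at
  $\theta$ contributes nothing to AUC or duration.
* **Denominator is total surgical duration**, including above-threshold
  time and gaps — not monitored time. Missing samples are excluded from
  numerators, retained in the denominator, and a gap fraction above 10%
  flags the series (`gap_flag` in `threshold_burden()`).
* TWA is displayed at 2 decimals in reports; internal values are never
  rounded. The identity `TWA × total duration = AUC` holds to machine
  precision and is asserted in the tests.

Hypertension burden (overtreatment surveillance) mirrors the definition
above the 130 mmHg threshold.

## The synthetic cohort

No patient-level data from such trials are public, so the generator is a
first-class, tested module whose defaults encode the study conditions the
analysis assumes: 30 patients per arm under 1:1 allocation, vital signs
every 20 s, an alarm threshold of 85 on the 0–100 index, clinicians
acting within 2 min of an alarm, and reactive treatment at MAP < 65 mmHg
in the control arm.

**MAP dynamics.** A discrete-time mean-reverting update at the sampling
cadence,

$$m_k = m_{k-1} + \theta_{\mathrm{OU}}\,(T_k - m_{k-1})\,\Delta t +
\sigma\sqrt{\Delta t}\,\varepsilon_k,$$

clamped to 20–200 mmHg, with set-point $T_k$ = patient baseline
(population $85 \pm 7$ mmHg) + active provocation offset + active
treatment effect. Defaults: reversion rate $\theta_{\mathrm{OU}} = 0.5$
/min (a ~2-min time constant, the scale on which pressure responds to a
changed physiological state) and diffusion $\sigma = 3$ mmHg/√min, which
gives a stationary wiggle of about ±3 mmHg — realistic short-term MAP
variability without spurious threshold crossings from noise alone. No
published signal model exists for this setting; this is the simplest
process with realistic autocorrelation.

**Provocations.** Hypotensive episodes arrive as a Poisson stream
(default 1.2/h) of set-point drops, uniform on −35 to −22 mmHg, lasting
an exponential time (mean 8 min, floored at 2 min), each with a
physiological cause (preload deficit, vasomotor failure, or depressed
contractility) that also shapes the auxiliary channels the decision
protocol reads. The depth range was calibrated once so that a typical
provocation drives MAP 2–15 mmHg below 65 from an average baseline —
deficits that a single protocol-dosed treatment (amplitude 15–30 mmHg)
can realistically cover, which is what published severity figures for
both arms imply. Against the trial-scale reference magnitudes (control
median TWA-MAP<65 near 0.3–0.4 mmHg, intervention several-fold lower) the
defaults land in the right regime without per-seed tuning.

**The index proxy.** The real predictive index is proprietary; the
analysis only needs its *predictive-lead* property. The proxy projects
the untreated mean path from the current value toward the currently
active set-point (the noise-free relaxation), takes the projected minimum
over the next 15 min, and maps it through a logistic centred so that
index > 85 exactly when that projected minimum is below 65 mmHg, plus
bounded noise (`index_noise_sd`, truncated at 2.5 SD, clamped to 0–100).
Two consequences, both tested:

* with noise off, every sustained sub-65 crossing is preceded by an
  index exceedance with positive lead time (the silent-alarm
  reconstruction is well-posed by construction);
* the projection conditions on the *current* state only — the index
  reacts when a deterioration begins, not before, so alarm lead times are
  a few minutes (the relaxation time from baseline to the threshold), not
  the full 15-min horizon. The index is computed from the untreated path:
  a predictive index forecasts what would happen absent intervention, and
  computing it from the treated path would cancel its own alarms.

**Treatment triggering and pharmacodynamics.** In the intervention arm, a
treatment follows each merged (15-min anchored) alarm after a lognormal
delay with median 42 s clamped to the 2-min action window. In both arms a
reactive standard-of-care rule backstops breakthrough hypotension: each
new sub-65 crossing outside the previous 15-min window triggers a
treatment after a delay with median `control_detection_delay_s` (40 s).
The option is chosen by the decision protocol from the auxiliary
snapshot at the anchor; vasopressor-type options inject an
instantaneous-onset, exponentially decaying set-point pulse (amplitude
uniform on 15–30 mmHg, decay constant 20 min), fluid-containing options
ramp in linearly over 5 min. No published dose–response exists for this
setting; amplitudes and decay are configurable.

**Covariates.** Age ~ N(60, 10.5²) truncated to the 20–80 inclusion
range, 80% male, surgery mix of pancreas/oral/esophagus at roughly a
third each, and lognormal surgical duration with median 490 min (clamped
to 3–16 h) — the demographic margins typical of long oncological surgery
in this literature. No dropout is simulated (completion of all
randomized patients is the reference condition).

**Reproducibility.** One global seed expands into per-patient substreams
via a stable polynomial hash of the patient id, with fixed offsets per
stage (covariates, MAP, index, treatments). Adding patients therefore
never perturbs existing ones, and the treated path reuses the untreated
path's innovations so that enabling treatments is a paired, same-noise
comparison.

**What the generator does not emulate.** No beat-to-beat waveform (all
analyses operate on the 20-s cadence), no artifacts or monitor gaps, no
drug-specific kinetics or cumulative dosing, no circadian or surgical-phase
structure, no postoperative course. Passing tests therefore demonstrate
the correctness and internal consistency of the *analysis chain* and the
directional behaviour of alarm-guided management under the stated model —
not the clinical magnitude of the effect in real patients.

## Event analytics

* **Episode definition:** MAP < 65 mmHg sustained ≥ 1 min (≥ 3
  consecutive samples at 20 s). The minimum duration applies to event
  detection only, never to burden metrics, whose definition has no
  duration clause.
* **Alarms:** strict exceedance (index > 85), one event per upward
  crossing.
* **Merging is anchored, not chained:** the first event fixes a 15-min
  window; everything inside merges into it; the first event at or beyond
  the window's end is the next anchor. Chained merging would silently
  extend windows. Windows are closed on the left, open on the right; time
  is 0-based seconds from the first sample.
* **Silent alarms:** for each merged hypotension anchor in the reactive
  arm, the earliest index exceedance within the 15 min *preceding* the
  onset (inclusive). The backward reading is forced by prediction
  semantics — the index rises before the event. Anchors with no
  exceedance are counted as unreconstructable rather than imputed.
* **Latencies:** each anchor is matched to the first treatment at or
  after it within its 15-min window; a treatment can satisfy only one
  anchor (greedy, earliest first). Unmatched anchors are reported as
  untreated, not dropped.

## The decision protocol

The six-option table is *data*, not code: an ordered rule list over
configurable thresholds (`svv_high` = 13%, `eadyn_high` = 0.9, `svr_low`
= 800 dyn·s·cm⁻⁵, `dpdtmax_low` = 600 mmHg/s). Published protocols of
this family specify the traversal order — preload, then vasomotor tone,
then contractility — but print the cut-offs only in figures; the defaults
here are configurable surrogates in the conventional clinical range, not
authoritative constants. Dynamic arterial elastance arbitrates within the
preload-positive branch (fluid raises pressure only when elastance is
high). Rules are evaluated in fixed order and the first complete path
wins; the traversal is returned as `rationale_path`, making every
recommendation auditable. Totality (every finite input yields exactly one
of the six options) and preload monotonicity (raising SVV never removes
fluid from the recommendation) are tested over exhaustive grids.

## Statistics

* **Mann–Whitney U:** exact enumeration of all rank assignments (valid
  under ties) when either group has fewer than nine observations; the
  tie-corrected normal approximation without continuity correction
  otherwise. Two-sided p by tail doubling, capped at 1; identical
  constant samples give p = 1.
* **Hodges–Lehmann:** median of all pairwise differences (oriented
  `y − x`), Moses interval on the ordered differences with exact
  rank-sum critical values up to 100 per group and the normal
  approximation beyond.
* **Means:** pooled-variance t-test from summary statistics, with CIs
  from t critical values at pooled df. A z-based "large-sample" interval
  misses published reference values by ~14 mL on the fluid-balance row;
  the t-based construction reproduces them, so it is the default.
* **Proportions:** Pearson chi-square without Yates correction (the
  corrected statistic fails to reproduce published reference p-values),
  Fisher's exact test (two-sided as the sum of point probabilities ≤
  observed; the doubling convention is documented but off), selection by
  the expected-count rule (Fisher iff ≥ 50% of expected cells < 5), and
  continuity-corrected Wald intervals for proportion differences. One
  published reference row (a perfectly balanced 8/30 vs 8/30 table)
  reproduces only under the *uncorrected* Wald interval while three
  others require the corrected one — an internal inconsistency of the
  source material; the corrected form is implemented.
* **Sample size:** smallest equal per-group n whose noncentral-t power
  for the two-sided pooled t-test reaches the target, then dropout
  inflation by `ceiling(n / (1 − dropout))` rounded up to even for 1:1
  allocation. At the reference design values (0.15 vs 0.40, SD 0.32,
  α = 0.05, power 0.80) this returns 54 and 60.
* **Multiplicity:** Bonferroni over the postoperative-outcome family.

## Problem sizes and degenerate inputs

The test suite runs the full chain at trial scale (30 patients per arm)
across ten seeds for the directional replication, and at 2–10 patients
per arm elsewhere; property checks use 1000 random series for the burden
oracle and exhaustive small-grid enumeration for merging and the
protocol. These sizes were chosen as the smallest that exercise every
code path at trial-realistic scale. Degenerate inputs are rejected
loudly: empty series and zero-margin tables raise errors distinct from
zero burden, zero-length event lists flow through merging and latency
matching as empty results, and all-zero outcome columns (e.g.
hypertension burden when no one crosses 130 mmHg) yield p = 1 rather
than NaN.

## Known limitations

* The index proxy shares only the lead-time property with proprietary
  predictive indices; receiver-operating characteristics are not
  calibrated to any published index.
* Treatment counts per patient run somewhat higher in the alarm-guided
  arm than published trials report, because every merged alarm triggers
  exactly one treatment and breakthrough rescues add to it; the trial
  endpoints studied here (burden, latency) are insensitive to this.
* Group-level magnitudes depend on the provocation calibration; only the
  direction and approximate scale of the arm contrast — not printed
  group medians — should be compared against any specific trial.
* The report tables cover baseline, burden/behaviour and treatment-usage
  structure; postoperative outcome tables are placeholders by design,
  since the generator does not simulate the postoperative course.
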