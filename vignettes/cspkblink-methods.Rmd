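---
title: "Methods: eyeblink conditioning and complex-spike analysis with cspkblink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eyeblink conditioning and complex-spike analysis with cspkblink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`cspkblink` implements the desk-scale analysis of a delay
eyeblink-conditioning experiment in head-fixed mice: eyelid videometry,
conditioned-response (CR) scoring, Purkinje cell simple-spike
(SSpk)/complex-spike (CSpk) train statistics, classical group
comparisons, and fiber-optic irradiance prediction. Because raw animal
recordings are not distributable with a package, a synthetic-session
generator emulates every input modality with stored ground truth, making
the entire pipeline testable end to end.

## The behavioral protocol and its generator

A session presents 100 trials: 90 pairings of a visual conditioned
stimulus (CS) with an airpuff unconditioned stimulus (US), and 10
CS-only probe trials at random positions. The CS precedes the US by a
fixed 300-ms interstimulus interval (ISI) and the two stimuli
co-terminate; intertrial intervals are drawn uniformly from 10-15 s.
`generate_session()` reproduces exactly this structure (all of it
configurable through `session_config()`).

`generate_behavior()` synthesizes normalized eyelid-closure traces
(0 = maximal opening, 1 = full closure):

* **UR** (unconditioned response): every airpuff trial carries a
  reflexive closure of amplitude 1.0 beginning 20 ms after airpuff
  onset, with a 15-ms raised-cosine rise, a plateau through the 50-ms
  puff, and an exponential decay (default time constant 100 ms). The
  latency and full amplitude are generic rodent blink kinematics; no
  quantitative UR kinematics are prescribed by the protocol, so these
  values are plausible placeholders chosen once, not measurements.
* **CR**: each CS-containing trial independently carries a learned
  closure with probability `p(s) = p_max (1 - exp(-s / tau))` of the
  training-session index `s` (saturating acquisition; an extinction
  mode decays instead). The CR waveform is a raised-cosine bump
  (half-width 250 ms) peaking at the expected US arrival time
  (`cr_peak_time`, default = ISI) with 10-ms trial-to-trial jitter.
  The raised cosine is a smooth, peak-parameterizable shape chosen for
  convenience; real CR kinematics are asymmetric, but only the peak
  amplitude and timing matter for every statistic computed downstream.
* Additive Gaussian noise (sd 0.02 normalized units), clipped to
  [0, 1].

The generator imposes CR schedules; it does not model plasticity, so
nothing downstream can "discover" learning mechanisms - tests only ever
verify that imposed parameters are recovered.

## Videometry

`render_video()` inverts the measurement model: each 172 x 160 px,
900-fps frame shows a bright filled ellipse (the open eye) on a dark
background, with fixed major axis (100 px) and minor axis
`round(a_open * (1 - closure))` for `a_open = 60` px, plus Gaussian
pixel noise (sd 5 gray levels by default).

`segment_frame()` recovers the eyelid distance: binarize, keep the
largest connected component (EBImage's labeling), fit an ellipse by
second-order image moments, return the minor-axis length. Choices the
measurement description leaves open, fixed here explicitly:

* **Threshold policy.** Default is Otsu's method per frame, with a
  fixed-gray-level override. The threshold is computed from the
  tabulated 256-bin histogram; when the two modes are cleanly separated
  the between-class variance is flat across the empty valley, and the
  plateau midpoint is taken, which maximizes the margin to both modes
  (a test pins this to EBImage's reference implementation within 2 gray
  levels).
* **Polarity.** Bright eye on dark background; an `invert` flag handles
  the opposite contrast.
* **Floors.** Components under 20 px^2 are noise specks; frames whose
  gray-level range is below 50 are featureless (fully closed eye) and
  return distance 0.

`normalize_session()` calibrates distance to closure per session:
`d_open` is the 99th percentile of distance across the session (robust
"maximal opening") and `d_closed` the median over airpuff trials of the
minimum distance within 200 ms of puff onset ("full closure under the
airpuff"); percentile/median forms resist single-frame artifacts.
Closure is `(d_open - d) / (d_open - d_closed)` clipped to [0, 1]; a
session with no airpuff trials needs an explicit `d_closed`, and
`d_open == d_closed` is a degenerate-calibration error. The round trip
render -> segment -> normalize recovers programmed closure with RMS
error well under 0.03 at default noise (the discretization floor alone
is ~1/120 of the open-eye axis).

## CR scoring

`detect_cr()` applies the standard rule: a trial contains a CR if the
baseline-subtracted closure strictly exceeds 0.1 at some time more than
100 ms after CS onset and before US onset (CS-only trials: before the
nominal US time). Two additions make the rule robust on sampled data,
both configurable:

* baseline = mean closure over the 200 ms before CS onset;
* the crossing must be sustained for 10 ms (9 frames at 900 fps), so a
  single noisy frame cannot score as a CR.

Deflections in the first 100 ms (startle window) are ignored entirely
rather than disqualifying the trial. The %CR denominator defaults to
all CS-containing trials (paired + probe); a `cs_only` mode restricts
it to probe trials, since either reading of a single per-session %CR is
defensible. Raising the amplitude threshold can only remove CRs, a
monotonicity the test suite checks exactly.

`cr_timing()` reads the learned-response peak off the averaged CS-only
trace in the window from CS onset to 200 ms past the nominal US time;
ties take the first index, so a constant trace reports the window start
with amplitude 0.

## Spike trains

`generate_spike_train()` draws ground-truth event times: SSpks as a
gamma renewal process (default rate 80 Hz, shape 4, i.e. ISI CV 0.5,
typical of regular Purkinje firing; shape 1 recovers a Poisson train
for analytic tests) with a 1-ms absolute refractory period; spontaneous
CSpks as a Poisson process (default 1 Hz) with a 5-ms minimum
separation - small enough that the exponential interval law is
essentially intact (the doublet-fraction limit shifts by under half a
standard error at the sizes tested); and evoked CSpks with probability
`p_evoked` (default 0.9) at latency Normal(20 ms, 3 ms) after each
airpuff. Every CSpk silences SSpks for 20 ms and carries 2-6 spikelets
at 2-ms spacing. `generate_voltage()` renders these times at 25 kHz:
a fixed biphasic kernel (negative-going primary trough) per SSpk, a
1.5x-amplitude primary followed by geometrically decaying spikelet
copies (factor 0.7) per CSpk, plus white Gaussian noise (sd 0.05
against a unit SSpk amplitude). The geometric decay makes spikelet
counting nontrivial but well-posed at default noise.

`detect_spikes()` thresholds at `k = 4.5` times the robust sigma
`median(|x|) / 0.6745` (MAD-based, insensitive to the spikes
themselves), takes local extrema of supra-threshold excursions with a
1-ms dead time, and cuts -1/+12-ms snippets. At the default k the
false-positive rate on pure Gaussian noise stays below 0.1 Hz. A flat
trace (sigma 0) is a degenerate-signal error.

`classify_events()` replaces a learned sorter with a deterministic,
parameter-explicit rule built on the CSpk signature (initial spike,
spikelets, SSpk pause): an event is a CSpk iff at least 2 secondary
peaks of amplitude 25-90% of the primary occur within 10 ms after the
primary peak and no further detected event follows within 8 ms after
that window; detected events inside an accepted CSpk's window are
absorbed as its spikelets. The 90% upper bound is essential: without
it, ordinary follower SSpks at short gamma ISIs (about 4% of events at
80 Hz, shape 4) read as "spikelets" and whole triplets of SSpks get
absorbed into spurious CSpks; with it, label accuracy against ground
truth exceeds 0.99 at default SNR. The bound encodes the defining
feature that spikelets are smaller than the initial spike.

## Unit statistics

`unit_stats()` computes, per unit: spontaneous SSpk/CSpk rates, SSpk
ISI CV, post-CSpk pause (mean delay from each CSpk to the next SSpk),
CSpk doublet fraction, and evoked CSpk probability/latency.
"Spontaneous" means at least 0.5 s away from any CS/US/laser event -
the margin is this package's choice, as is the 60-s minimum spontaneous
time below which rate estimates error out. ISIs spanning an epoch
boundary are discarded. The doublet statistic is the fraction of
consecutive spontaneous inter-CSpk intervals under 200 ms (a per-event
reading of "CSpks within 200 ms of each other" is nearly identical for
the rates involved); it is undefined (NA) below two spontaneous CSpks.
For Poisson CSpks at rate r the expected fraction is `1 - exp(-0.2 r)`,
an analytic limit the tests check.

`psth()` bins SSpk counts (rate = count / (trials x bin width), 25-ms
default bins) and per-trial CSpk occurrence probability in half-open
bins; the count-conservation identity `sum(rate) x bin width x trials =
total count` is exact by construction. `evoked_response()` uses the
window (0, 50] ms after the event - wide enough for airpuff-evoked
latencies, short enough that spontaneous CSpks at ~1 Hz contaminate
under 5% of trials. `qualify_unit()` records both unit-inclusion
criteria: at least one spontaneous CSpk (the conventional criterion)
or laser-evoked probability above 0.5, which rescues units whose
spontaneous complex spiking is suppressed - the selection-bias scenario
that motivates recording both.

For population comparisons, `sample_unit_params()` draws per-unit rates
and regularity from population laws (SSpk rate Normal(80, 10) Hz
truncated at 30; ISI gamma shape uniform on [3, 6]; CSpk rate
Normal(1.0, 0.3) Hz truncated at 0.3). This between-cell spread is a
deliberate part of the simulated study conditions: with identical
units, group tests would resolve the generator's small deterministic
couplings (fewer CSpks means fewer post-CSpk pauses, nudging measured
SSpk rate and CV by under 1%), an artifact real cell-to-cell
variability buries. The channelrhodopsin-expression phenotypes scale
(CSpk rate, evoked probability, evoked latency) by (0.5, 0.2, 1.5) for
`CF_CHR2` and (0.85, 0.85, 1.1) for the low-expression `CF_CHR2_LE`,
so that high expression separates from control on evoked CSpk
probability but not on SSpk statistics, and low expression separates
on nothing - the qualitative population signature the acceptance suite
verifies with 10 units per group and 200 airpuff trials per unit.

## Group comparisons

`two_sample_ttest()` is the classical pooled-variance Student form
(df = n1 + n2 - 2), two-tailed, as conventional in this literature; a
Welch flag exists. `paired_ttest()` tests the differences with
df = n - 1. Constant samples with equal means give t = 0, p = 1;
constant samples with unequal means have no valid statistic and raise
an error. Significance coding: `*` p < 0.05, `**` p < 0.01, `***`
p < 0.001. No multiple-testing correction is applied and no normality
testing is performed, matching standard practice in the experimental
literature this pipeline serves; raw p values are reported.

## Fiber irradiance

`predicted_irradiance()` returns `P / (pi d^2)` for power `P` and core
diameter `d` - the peak irradiance at the depth where the diverging
beam's diameter has doubled relative to the core. The convention is
inferred, not taken from a stated formula: it is the effective-area
model that reproduces the standard calculator's worked values for a
100-um, 0.22-NA fiber (6 mW -> 190.9, 3 -> 95.5, 12 -> 381.8,
3.3 -> 105 mW/mm^2) to within 0.5%, which the test suite verifies.
Under this convention the maximum predicted irradiance is independent
of NA (the NA argument is validated but does not enter the formula),
and irradiance is strictly linear in power.

## Container format

Sessions serialize to a plain-text directory: `session.yaml` (config,
provenance, voltage sampling metadata), `trials.csv`, `eyelid.csv`
(long format), `video/trial_<id>.tif` (multi-page 8-bit grayscale
TIFF), `voltage.csv`, and `ground_truth/*.csv` for synthetic sessions.
The layout is this package's own and is not claimed compatible with
any public dataset's layout. Reading is tolerant of absent optional
assets and strict about schema violations (errors name the offending
row and column).

## Problem sizes and runtime choices

The test suite exercises the pipeline at sizes chosen to keep stochastic
bands tight while remaining desk-scale: videometry round trips over 20
trials of 1.5 s at 900 fps; CR-probability recovery over 100-trial
sessions at p in {0, 0.3, 0.7, 1.0} against binomial 99% intervals;
spike-pipeline recovery over 100 s of 25-kHz voltage (~8,000 events);
analytic limits over 1,000 s of CSpks and 300 s of Poisson SSpks; and
phenotype discrimination with 10 units per group, 200 trials each. A
full 900-fps video stack occupies ~150 MB per 1.5-s trial in memory, so
video work streams render -> extract one trial at a time;
`render_session_video()` holds all stacks and is only for small
sessions.

## Limitations

* The generator emulates signal statistics, not biology: no plasticity
  linking CSpks to later CR probability, no biophysical neuron model,
  no eye-region appearance variation (lashes, whiskers, illumination
  drift). Passing round-trip tests shows the measurement chain is
  faithful to this model, not that it is robust to every artifact of
  real video or electrode drift.
* Single-unit voltage traces are assumed (as with cell-attached
  recordings); there is no multi-unit separation or drift correction.
* The CR rule's baseline window, sustain requirement, PSTH bin width,
  evoked window and spontaneous-epoch margin are explicit stand-ins for
  choices the underlying measurement description leaves unstated; all
  are configurable and logged by `run_pipeline()`.
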