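---
title: "Methods: the rise-to-threshold model and the analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the rise-to-threshold model and the analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovisearch)
```

## The decision model

Egg laying in *Drosophila* proceeds through a stereotyped sequence:
ovulation (a standstill of about a minute while the egg passes into the
uterus), a search period in which the fly walks and evaluates
substrates, an abdomen bend, and deposition roughly 3 s after the bend.
We model the decision to terminate search as a rise-to-threshold
process. After each ovulation a latent variable $A(t)$ starts at
`reset_level` and evolves as

$$\mathrm{d}A = r\bigl(v(s(t))\bigr)\,\mathrm{d}t + \sigma\,\mathrm{d}W,$$

where $s(t)$ is the substrate under the fly and $r$ maps its current
relative value to a drift rate. On the favoured substrate
$r = r_\mathrm{hi}$. On the disfavoured substrate the drift starts at
$r_\mathrm{lo}$ and relaxes exponentially toward $r_\mathrm{hi}$ with
timescale $\tau_v$ measured from the last visit to the favoured option:

$$r(t) = r_\mathrm{hi} - (r_\mathrm{hi} - r_\mathrm{lo})
         \, e^{-\Delta t / \tau_v}.$$

This is the simplest process consistent with three observations: the
somatic calcium signal of the egg-laying command neurons dips at
ovulation, drifts up and down during search in a manner influenced by
substrate value, and reaches a consistent level just before the abdomen
bend; choice is governed by *relative* value (200 mM sucrose is avoided
against 0 mM but chosen against 500 mM); and egg laying on the
disfavoured option recovers over roughly two minutes after the fly last
left the favoured one. When $A$ crosses `threshold_level`, the abdomen
bend is emitted; the fly stands still from the bend through deposition
(real flies bend and deposit in place), the egg is deferred while the
fly is on the plastic barrier strip (flies do not lay on plastic), $A$
resets, and an inter-egg refractory period begins. The model never
writes down *why* values re-adapt; $\tau_v$ is purely phenomenological.

A crossing always resets $A$, whether or not an egg follows (depositions
interrupted by the session end are dropped); occasional egg-less
threshold events in real recordings are treated the same way.

### Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `threshold_level` | 1 | latent | sets the latent scale |
| `reset_level` | 0 | latent | post-egg reset |
| `drift_rate_high` | 0.02 | s⁻¹ | 50 s deterministic crossing; searches of tens of seconds to minutes |
| `drift_rate_low` | −0.03 | s⁻¹ | the signal can fall on a low-value substrate; strong enough that threshold crossings on the disfavoured option are rare right after a transition |
| `noise_sd` | 0.03 | s⁻¹ᐟ² | "highly variable" search durations (first-passage CV ≈ 0.2–0.4) without letting diffusion dominate the value signal |
| `value_adapt_tau` | 120 | s | the ~2 min recovery of egg laying on the disfavoured option |
| `ovulation_duration_mean` | 60 | s | ~1 min ovulation standstill (Gamma-distributed, shape 8: strictly positive, unimodal) |
| `bend_to_deposit_delay` | 3 | s | delay between bend completion and egg deposition |
| `inter_egg_refractory` | 30 | s | ovulation tends to follow the previous egg quickly |

`drift_rate_low` and `noise_sd` are the two values the source
experiments do not pin down individually; they were calibrated jointly,
once, so that pooled cohorts lay ≥90% of eggs on the favoured option
(the headline behavioural observation) while search durations stay in
the observed seconds-to-minutes range — after which they were frozen.
With these defaults 200-fly cohorts place 95–96% of eggs on the
favoured half in both 0 vs 200 mM and 200 vs 500 mM chambers.

### Locomotion

Locomotion is a two-state walk/pause Markov chain at the video frame
rate with a persistent-heading random walk during walking and
reflecting chamber walls; positions are folded into the chamber by
triangle-wave reflection. Two parameter sets are used: outside search,
bouts and pauses average ~10 s each; during search the fly walks almost
continuously with only brief pauses (mean ≈ 1.7 s), reflecting the
elevated locomotor activity of searching flies — without this the
speed-based search-onset detector would latch onto ordinary resting
pauses rather than the ovulation standstill. Defaults (walk 2.5 mm/s,
heading SD 1.0 rad/frame, frame rate 2 Hz, 40×40 mm chamber) give
midline transitions every ~40 s on average, inside the 30–120 s range
the downstream analyses assume. Only these occupancy statistics matter
downstream; the model makes no claim about path shape.

The half with the lower sucrose concentration is the favoured option.
With equal concentrations (island controls) both halves receive
$r_\mathrm{hi}$.

### The gentle-hyperpolarization variant

`kir_mimic_params(params, factor = 0.4)` models a moderate
hyperpolarization of the decision neurons as a uniform attenuation of
their synaptic drive: `drift_rate_high`, `drift_rate_low` **and**
`noise_sd` are all scaled. Scaling only the deterministic drift would
leave the unscaled diffusion to dominate threshold crossings and would
*reverse* the observed choice effect; attenuating the whole drive slows
the rise (median search duration grows ≈4×, versus the observed two- to
threefold) while giving the fly more substrate encounters per decision,
which raises the preferred-substrate fraction (≈ +2 points at cohort
scale with the defaults).

## The analysis pipeline

**Search onset.** The speed trace up to the deposition frame is smoothed
with a centred 18.5 s boxcar (truncated at the trace ends) and the
search start is the latest frame at which the smoothed speed falls below
0.1 mm/s — the end of the ovulation standstill. The returned duration is
floored at 9 s: a fly walking continuously up to deposition has no
sub-threshold frame and receives the 9 s fallback, and a fly still at
deposition is clamped to 9 s; both cases are flagged. Against simulated
ground truth the detector carries a constant bias of about +9 s (half
the smoothing window, as the window edge reaches back into the
standstill); this bias is inherent to the filter definition and is left
uncorrected, matching how the detector is defined.

**Transitions.** Raw transitions occur at every change of the per-frame
substrate assignment (centroid side of the midline; exact midline frames
go to the lower side — any fixed convention suffices for a measure-zero
set). One de-rocking pass over the raw list removes each transition
whose two neighbours fall within 4 s of each other. The pass is not
iterated to a fixed point; the rule is applied literally to the original
sequence.

**Rate curves.** For each elapsed-time bin (time since the most recent
transition, counted whether or not it occurred within the current search
period; before any transition, time since session start, flagged),
`rate = 120 × n_eggs/n_frames` at 2 Hz. The confidence interval is
computed on `n_eggs/n_visits` with the Clopper–Pearson method and
transformed by `120 × n_visits/n_frames`; computing it on
`n_eggs/n_frames` directly would make it frame-rate dependent. A visit
is an entry of the (direction, bin) assignment — the counter does not
increment while the fly stays in a bin frame to frame, and padding
frames accrue visits like any others. Searches shorter than 30 s are
padded to 30 s by extending the start earlier; padded frames inherit
the elapsed values they would have had. Default bin edges are geometric
(`default_rate_bins()`); per-bin values change with binning but the
early/late suppression contrast does not.

**ΔF/F.** Background is subtracted first
($F_\mathrm{actual} = F_\mathrm{cell} - F_\mathrm{background}$), the
baseline $F_0(t)$ is a centred 20 min running mean of
$F_\mathrm{actual}$ truncated at the recording edges (a trailing window
would delay the baseline; the fixed-$F_0$ variant behind `f0 = "fixed"`
bounds the impact of this choice), and
$\Delta F/F = (F_\mathrm{actual} - F_0)/F_0$. With an optogenetic
schedule, 105 s after each stimulation onset is set to NaN before the
baseline is computed. Samples with $F_0 \le 0$ become NaN and are
counted in an attribute. Traces are placed on a common 10 Hz grid by
previous-neighbour assignment. Event-triggered ensembles drop, for each
trace, all samples at or after the next exclusion event (e.g. a return
transition), so the post-event average is never contaminated by data
from after the fly returned. Multiple simultaneously imaged cells are
averaged within fly first, then across flies.

**Slope to threshold.** ΔF/F is smoothed with a 5 s boxcar; the signal
minimum after ovulation start is located, then the first subsequent
time the smoothed signal reaches 0; the net slope runs from there to
3.3 s before bend completion (approximately when the bend starts).
Traces that never re-reach 0 are flagged and excluded from group
statistics.

**Stimulation binning.** Each stimulation is assigned to one of seven
bins by its maximum ΔF/F 1–3 s after onset. The outer bins catch values
below 0.02 and at/above 0.52; the five interior bins are 0.10 wide —
the interior edges are a package choice (only the outer edges and the
bin count are fixed by the protocol) and are overridable. The
behavioural change is reported as post (2–4 s) minus pre (−2–0 s);
the sign convention is documented rather than inferred from prose.

**Spikes and the forward model.** Spikes are peaks of the high-passed
(2nd-order zero-phase Butterworth, default 100 Hz) membrane potential
above a threshold, with peaks closer than 1 ms resolved by keeping the
larger; cutoff and threshold are per-recording judgements in practice,
so both are parameters (default threshold 6 robust SDs of the filtered
trace; peaks inside a short guard band at the trace ends are ignored to
avoid zero-phase filter edge transients). Sliding rates count spikes in
5 s (or 100 ms) windows at 0.1 ms steps, dividing by the window and
assigning to the window centre. De-spiking blanks 150 ms centred on
each peak, merging overlaps. The junction correction subtracts 13 mV
exactly once and refuses a second application. The forward model
convolves a rate trace with a unit-area causal exponential
(τ = 300 ms, the indicator off-kinetics) and then a centred 2.8 s
boxcar (the slowest volumetric frame period); unit-area normalisation
is a package choice so that a constant rate maps to a constant proxy —
only the temporal shape is interpreted. Half-decay is the time after
stimulation end for the trace to return half-way between its
end-of-stimulation value and the mean over the 5 s preceding
stimulation onset, linearly interpolated between samples.

**Motif queries.** Duplicate (pre, post) rows are summed before the
ten-synapse threshold is applied. A single-intermediary loop for a seed
class is any non-seed cell receiving a thresholded connection from a
seed cell on the left and sending one to a seed cell on the right *and*
vice versa; the seed cells on the two legs may differ (the verbal motif
description does not require them to coincide), and a one-directional
relaxation is exposed via `require_both_directions = FALSE`. Gap
junctions are out of scope (not annotated in the source connectomes).

## Statistics

`clopper_pearson` uses the standard beta-quantile bounds, exactly 0/1
at the boundaries. `binary_group_ranksum` compares two groups of 0/1
trials; because the data are binary, the permutation distribution of
the rank statistic is hypergeometric in the group-1 event count, so the
test is exact for combined samples up to 200 and uses the tie-corrected
normal approximation (no continuity correction) above that — the
convention behind published large-sample rank-sum p-values on such
counts, and the two regimes agree in their overlap.

## What the synthetic data do and do not emulate

The generator reproduces the *statistical structure* the analyses
assume: ovulation standstills of ~1 min, variable search periods,
≥90% of eggs on the higher-relative-value half, suppression of
disfavoured-substrate egg laying that recovers over ~2 min, substrate
transitions every ~40 s with occasional long stays, no eggs on the
barrier strip, fluorescence with a rising latent signal plus baseline
drift and noise sampled at 1.5 Hz with half-volume timestamps, spike
trains, and synapse tables with planted motifs among weak distractors.

It does **not** emulate: pose or video (positions are generated
directly, not tracked); the ovulation-associated dip of the calcium
signal (the latent variable simply rests at `reset_level` between
searches); substrate-dependent settling (occupancy is ~50/50, whereas
real flies bias their time toward the favoured side); heavy-tailed
stay durations (stays are roughly exponential, so elapsed times beyond
~10 min are rare, while real sessions reach hours); or failed
crossings with partial resets. Consequently, passing tests show that
the estimators are correct on data satisfying their assumptions — not
that real recordings satisfy those assumptions.

Two measured divergences worth knowing about. First, the simulated
*favoured*-substrate rate curve is not flat: it climbs with elapsed
time on the substrate (long favoured stays accumulate complete egg
cycles), whereas the observed curve plateaus within tens of seconds;
the tests therefore assert the disfavoured-substrate suppression and
recovery, not favoured-curve flatness. Second, the visit-based
confidence interval is slightly anticonservative when the egg-per-visit
probability is high (measured ~85–89% empirical coverage at 95%
nominal for p ≈ 0.3–0.4, versus ~95% for p ≤ 0.1): egg counts and
frame counts are negatively correlated under within-bin truncation, so
the `visits/frames` scale factor co-moves with the numerator. In the
regime the interval is scientifically used in — sparse egg laying on
the disfavoured option — it is near-nominal.

## Numerical choices

Threshold crossings are detected with a 10⁻⁹ slack so that exact
zero-noise arithmetic (e.g. a 50 s crossing at drift 0.02 s⁻¹) is not
broken by floating-point accumulation. Boxcar filters are centred,
NaN-aware (NaNs excluded from numerator and denominator) and truncated
at trace ends; even sample counts place the extra sample after the
centre. The running-mean baseline uses a true time window (findInterval
on timestamps), so irregular volume timing is handled. The exponential
stage of the forward model is implemented as the exactly-equivalent
first-order recursive filter, which preserves constants by
construction. Problem sizes in the test suite (cohorts of 12–60 flies
at 1–2 h, 1,000-replicate coverage simulations, 10 s voltage traces at
10 kHz) were chosen so the full suite runs in well under a minute while
keeping Monte-Carlo assertions far from their decision boundaries.

## Known limitations

- The simulator's locomotion is diffusive; spatial strategies
  (wall-following, spatial memory) are absent, and the observed tendency
  of flies to leave a disfavoured start substrate more often emerges
  only weakly.
- The hyperpolarization-mimic's search-duration effect (~4×) is
  somewhat stronger than the observed two- to threefold, and its
  choice-fraction improvement (~+2 points) somewhat weaker than
  observed; both directions are correct.
- Quantities measured from real recordings — the ~0.35 pre-bend ΔF/F
  level, the stimulation threshold, hyperpolarization depths, somatic
  and simulated half-decay times — are not reproducible from synthetic
  data; the corresponding machinery is verified against closed forms
  and brute-force oracles instead.
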