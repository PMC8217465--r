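---
title: "Detecting high-frequency oscillations and delineating the epileptogenic zone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting high-frequency oscillations and delineating the epileptogenic zone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfoloc)
```

## The problem

In drug-refractory epilepsy, surgical removal of the epileptogenic zone (EZ)
— the cortical tissue necessary and sufficient to initiate seizures — is the
main curative option. High-frequency oscillations (HFOs) in intracranial EEG
are a widely studied electrophysiological marker of epileptogenic tissue: an
HFO is a spontaneous oscillation at 80–500 Hz with at least four cycles that
clearly stands out of the background, subdivided into ripples (80–200 Hz)
and fast ripples (FRs, 200–500 Hz). FRs are considered the more specific
marker. `hfoloc` implements an automated ripple/FR detector, ranks channels
by HFO rate to delineate a putative EZ, and computes the cohort-level
statistics used to relate marked regions, surgical resections and Engel
outcomes across imaging modalities (PET-MRI and the FLAWS MRI sequence enter
only as sets of marked region labels).

## The detection pipeline

Recordings are assumed sampled at 4096 Hz (any rate above 1 kHz works) and
are first re-referenced to a **bipolar montage**: for each depth-electrode
shaft with $k$ contacts, the $k-1$ channels $x_i - x_{i+1}$ (low-minus-high
contact, stated explicitly because sign conventions differ between labs).
The analysis segment is 5 minutes of slow-wave sleep, selected as the
earliest run of ten consecutive 30-s epochs in which delta-band power
(0.5–4 Hz) exceeds 25% of broadband power (0.5–45 Hz). We read "delta
activity occupied more than 25% of background activity" as a relative
band-power criterion computed by averaged periodogram, taking the median
across channels per epoch; this is the only reading that is reproducible
from the iEEG alone (clinically it was verified with EMG/EOG, which we do
not model). Seizure-guard intervals can be supplied as explicit exclusion
windows.

Per channel and band, detection proceeds:

1. **Zero-phase FIR bandpass.** A linear-phase Hamming-window FIR
   (order 600) is applied with zero net phase shift. Rather than literal
   forward–backward filtering we multiply the reflection-padded signal's
   spectrum by $|H(\omega)|^2$, which is algebraically the same operation
   at $O(n\log n)$ cost. Order 600 at 4096 Hz gives a ~22 Hz transition
   band, so 50 Hz mains and delta/theta leakage are >40 dB down (doubled in
   the squared response) while the 80 Hz edge remains sharp.
2. **Peak extraction.** Strict local maxima of the absolute filtered
   signal; plateaus keep their first sample. Two peaks correspond to one
   oscillation cycle, so the eight-peak rule below encodes the
   four-oscillation minimum.
3. **PPDC baseline.** Within contiguous 5-s windows the peak amplitudes are
   sorted ascending — the peak point distribution curve. Its turning point
   is found by maximum perpendicular distance to the chord joining the
   curve's endpoints, with both axes min–max normalized so rank and
   amplitude are commensurate. Peaks strictly before the turning point are
   baseline points; their mean $\mu$ and standard deviation $\sigma$ set
   that window's thresholds. Windows with fewer than 20 peaks fall back to
   the whole-channel curve; a flat curve (all peaks equal) is degenerate
   and gets $\sigma = 0.05\,\mu$ so thresholds remain finite.
4. **Candidate events.** An event is a maximal run of at least eight
   consecutive peaks above $\mu + 3\sigma$ that contains at least six
   consecutive peaks above $\mu + 10\sigma$ (ripples) or $\mu + 9.5\sigma$
   (fast ripples). The high-threshold run must nest inside the
   low-threshold run; thresholds come from the window holding the run's
   first peak; events closer than 10 ms merge. Event start/end are the
   first/last qualifying peak times (half-open intervals).
5. **Gibbs rejection.** Sharp transients (interictal spikes) ring when
   bandpassed and mimic oscillations. For each candidate the *raw* segment
   (±50 ms margins) is examined: a Hann-windowed periodogram zero-padded to
   a 1 Hz grid, smoothed over ±10 Hz; with $f^*$ the in-band power maximum
   the statistic is $\Delta = P(f^*) - P(f_\mathrm{off})$, where
   $f_\mathrm{off} = \max(f^* - \tfrac12 \mathrm{bandwidth},\ 30\,$Hz$)$.
   A genuine oscillation contributes a local spectral peak ($\Delta > 0$);
   spike ringing rides the monotonically decreasing 1/f spectrum
   ($\Delta \le 0$) and the candidate is discarded. This spectral
   peak-versus-offset statistic is our documented stand-in for the original
   authors' unpublished "frequency offset power difference of phase space
   reconstruction": for narrowband signals a two-dimensional time-delay
   embedding radius is a band-power measurement, so the spectral form
   honors the same discrimination principle with a parameter-free
   definition.

Because every threshold is relative to the within-channel baseline, the
detector is invariant to rescaling a channel, and the zero-phase filter
keeps detected events aligned with the underlying oscillation (no
systematic midpoint shift). One caveat worth stating: event boundaries are
peak times, so a detected midpoint is quantized at half the inter-peak
spacing, $1/(4f)$ — 1.3–3 ms for ripples. Edge peaks sit near the 3 SD
threshold, so single-peak boundary jitter of that size is inherent to the
event definition, not a phase error of the filter; tests therefore hold
fast ripples to a 1 ms midpoint error per event and ripples to a 1 ms
median.

## EZ delineation

Channels are ranked by retained-event rate (descending, stable ties) using
fast-ripple counts whenever any retained FR exists, otherwise ripples (the
published fallback for FR-free patients). The EZ is the minimal top-ranked
prefix whose cumulative event count reaches 72% of all events in the chosen
band. The published threshold phrase ("top 72% channel distribution area")
admits a second reading — the top 72% of event-positive channels — which is
available via `ez_params(rule = "channel_fraction")`; with a single
fixed-duration segment the two readings rank identically and differ only in
where the prefix is cut. Zero-event channels are never part of the EZ, and
the EZ grows monotonically with the coverage parameter.

## Clinical concordance statistics

For cohort tables mirroring the 15-patient study layout (modality-marked
region label sets, removed set, Engel outcome):

* `ratio_chann(n_removed, n_nonremoved)`:
  $(\#\mathrm{Rem} - \#\mathrm{NonRem})/(\#\mathrm{Rem} + \#\mathrm{NonRem})$,
  the resected fraction of marked channels on a $[-1, 1]$ scale.
* `classify_outcome()`: Engel I → good, II/III → poor.
* `fisher_exact_two_sided()`: the probability method — enumerate all 2×2
  tables with the observed margins and sum hypergeometric probabilities no
  larger than the observed table's. This reproduces the published
  p = 0.007 (complete HFO removal vs seizure freedom) and p = 0.002
  (multimodal condition) exactly (0.006993, 0.001998).
* `wilcoxon_rank_sum()`: exact two-sided permutation p (midranks for ties,
  computed by a dynamic-programming convolution) for pooled n ≤ 20, which
  covers study-scale comparisons such as 5 vs 9 patients; a tie-corrected,
  continuity-corrected normal approximation beyond.
* `consistency()`: between two modalities, the fraction of evaluable
  patients whose label sets share at least one region, and the fraction
  with identical sets. `"/"` marks a missing modality (row excluded);
  `"Normal"` is an examined-but-clean empty set (evaluable). Labels are
  matched exactly after trimming, uppercasing and stripping annotations
  like `(#)`.
* `confusion_counts()`: outcome-anchored region bookkeeping. Good-outcome
  patients: marked∧removed → TP, marked∧retained → FP, plus one TN token
  for the unmarked remainder. Poor-outcome patients: marked∧removed → TP
  plus one FN token for the residual EZ; poor-outcome patients with
  retained marked regions are excluded outright because their retained
  marks cannot be classified. What constitutes one region "unit" is not
  standardized; our one-token-per-patient convention for the unmarked
  remainder is a documented choice, which is why published
  sensitivity/specificity percentages are reported but not asserted.
  We also compute specificity as TN/(TN+FP), the standard definition; the
  source text prints FP/(FP+TN), which we treat as a typographical slip.

The published per-patient completeness judgments came from post-surgical
imaging, not from the printed label sets (e.g. a seizure-free patient whose
printed HFO labels include a region absent from the printed resection
list). The published contingency panels are therefore shipped verbatim as a
fixture (`table2_panels()`), while `outcome_association()` derives panels
from explicit per-patient flags, as produced by the synthetic cohort
generator.

## The synthetic-data generator

The generator exists so that every pipeline stage is testable without
patient data. It emulates:

* **Background**: Gaussian $1/f^\alpha$ noise ($\alpha = 1$ by default) via
  spectral shaping of white noise, independently per channel, normalized to
  a target SD (default 20 µV). One master seed; per-channel streams derived
  by a fixed counter scheme, so output is bit-reproducible.
* **Bursts**: Hann-tapered sinusoids. Frequency must lie inside the band
  its kind names; `n_cycles >= 4` makes a burst nominally detectable.
  Amplitude is specified in multiples of the *band-filtered* local
  background SD (±0.5 s neighborhood). This is the scale on which the
  detector's relative thresholds operate: a 5× burst clears the 3 SD run
  but not the 10 SD run (not a candidate), while 10–15× bursts are
  detected. Specifying amplitude against the raw broadband SD would make
  every burst trivially detectable, because most 1/f power lies far below
  the detection bands.
* **Spikes**: monophasic Gaussian-envelope deflections (envelope SD =
  width/8, so the support is about the stated 10–80 ms width), scaled
  against the raw local SD since they are broadband. They are the
  false-HFO generator: at high amplitude their filter ringing passes both
  peak-run thresholds and only the Gibbs stage removes them.
* **Cohorts**: per-patient marked/removed label sets and Engel outcomes
  with a complete-removal probability conditional on outcome, so
  association tests have known structure.

What the generator does *not* emulate: ictal activity, realistic sleep
architecture (only delta-power modulation), electrode geometry, mains
interference, and non-stationary artifacts. Passing recovery tests
therefore demonstrate correctness of the algorithmic chain under the stated
signal model, not clinical performance on real iEEG.

## Study-scale test conditions and numerical choices

The recovery scenario used by the tests and the acceptance script matches
the study conditions: 10 bipolar channels × 5 min at 4096 Hz, 40 ripples +
20 fast ripples at 10–15× band SD and 30 spike transients (12–25× raw SD),
placed at random non-overlapping positions; burst frequencies are drawn
uniformly on 90–190 Hz and 220–480 Hz with 8–16 cycles. Measured on that
scenario the detector attains recall ≥ 0.95 with precision 1.0 (the
occasional misses are ~10× bursts within the filter transition band at the
200 Hz band edge), and 100 seeded spike-only recordings yield zero retained
events. Spike-only runs include amplitudes up to 60× SD precisely so that
some spikes *do* become candidates and the rejection stage is exercised
rather than vacuous.

Other conventions: times are seconds from recording start with half-open
intervals; an event belongs to the baseline window of its first peak;
baseline windows are contiguous and non-overlapping by default (a sliding
hop is available via `baseline_hop`); the Fisher enumeration uses the
customary $(1+10^{-7})$ slack when comparing table probabilities; EDF
export uses 1-s data records and 16-bit quantization over a per-channel
symmetric physical range (round-trip error below one quantization step).

## Known limitations

* The PPDC turning point on pure-noise channels lands near the 0.88
  amplitude quantile, so baselines sit 13–19% below the all-peak mean —
  harmless for detection (thresholds are far above either) but worth
  knowing when interpreting baseline summaries.
* The original turning-point ("maximum distributed peak points") and
  phase-space Gibbs algorithms are described only in prior publications we
  do not reproduce; our chord-knee and spectral-offset definitions are
  parameter-free stand-ins with switches (`baseline_hop`,
  `gibbs_offset_fraction`, `gibbs_min_offset_hz`) for substitution.
* Region-label matching is exact string matching; anatomical adjacency
  (e.g. a parietal label "overlapping" an inferior-parietal one) is out of
  scope, which is why some published cross-modality consistency counts
  that relied on anatomical judgment are reported but not asserted.
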