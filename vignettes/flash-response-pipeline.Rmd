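---
title: "Flash-response analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flash-response analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flashresp)
```

This vignette is the package's own account of the methods it implements:
the signal model behind the calcium-imaging pipeline, the statistics used
for the genetics readouts, the parameters that matter and their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the procedure left room for interpretation.

## The imaging pipeline

An ROI's raw fluorescence is modelled as a slowly decaying bleaching
envelope multiplied by stimulus-evoked calcium transients, plus noise:

$$F(t) = B(t)\,\bigl(1 + \textstyle\sum_j m\,k(t - t_j)\bigr) + \varepsilon(t),
\qquad
B(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2} + c .$$

Processing inverts this model stage by stage:

1. **Registration** (`register_frames()`): integer x/y translation
   maximizing correlation with the mean of the first frames. This handles
   slow drift of a head-fixed preparation; it is not a warping or
   rotation registration.
2. **Extraction** (`extract_roi_trace()`): the per-frame ROI pixel mean
   minus the mean over a background region without cells.
3. **Bleach correction** (`fit_bleach()`): a least-squares fit of the
   two-exponential envelope (with an additive offset by default), used as
   the baseline $F_0(t)$ at every frame.
4. **deltaF/F** (`compute_dff()`): $(F(t) - F_0(t)) / F_0(t)$.
5. **Stimulus locking** (`stimulus_locked_average()`): every frame time
   is reassigned relative to each transition of the requested type (after
   delay compensation), pooled over transitions, and averaged with a
   25 ms moving window stepped every 8.33 ms. A 38.9 Hz acquisition is
   thereby resampled onto a ~120 Hz grid with 3-point boxcar smoothing
   and no other distortion of the signal.
6. **Responder flag and peak** (`identify_responder()`,
   `peak_response()`): a response is the averaged value farthest from
   zero in the expected direction (a calcium increase for light flashes)
   within the response window; peaks are normalized per compartment to
   the mean of the no-Flp control so its mean is exactly 1
   (`normalize_peaks()`).
7. **Group statistics** (`anova_oneway()`, `posthoc_bonferroni()`):
   one-way ANOVA across the experimental and two control genotypes, then
   post-hoc Student's t-tests of experimental vs each control,
   Bonferroni-corrected; asterisks are displayed only when both
   comparisons are significant, at the tier of the less significant one.

### Which frames anchor deltaF/F = 0

Two window rules are implemented. `all_frames` (used with the slow
search stimulus) fits the envelope to the entire series, placing
deltaF/F = 0 at the mean response. `last_25pct_gray` (used with the
flash protocol) fits only frames in the final 25% of each gray period —
375 ms of the 1500 ms interleave — placing deltaF/F = 0 at the resting
baseline the cell returns to between flashes. A consequence worth knowing
for quantitative work: a transient that has not fully decayed 1.1 s after
onset leaks slightly into the fitted windows and biases recovered peaks
downward by a few percent at GCaMP6f-scale decay times. This is a
property of the baseline convention itself, not of the implementation,
and it is covered by the recovery tolerance below.

### Timing conventions

The projector updates on a discrete 8.33 ms stimulus frame, so physical
onsets lag nominal command times by a variable amount within one frame;
the measured mean lag is 6.25 ms. `compensate_delay()` adds this delay to
every logged transition once (a second application errors, preventing
double compensation). Frame times are frame-start times, 0-based, in
seconds. The quoted 240 Hz projector refresh and the 8.33 ms stimulus
frame (120 Hz) are mutually inconsistent as stated by the source
protocol; the package treats the 8.33 ms stimulus frame as the
authoritative jitter quantum.

### Key parameters

| parameter | default | units | role |
|---|---|---|---|
| `window_ms` | 25 | ms | moving-average width (3-point boxcar at 38.9 Hz) |
| `shift_ms` | 8.33 | ms | output grid spacing (~120 Hz) |
| `delay_ms` | 6.25 | ms | stimulus onset lag added to logged times |
| `window_rule` | `last_25pct_gray` | — | frames anchoring deltaF/F = 0 |
| `responder_k` | 3 | baseline SDs | responder threshold |
| `threshold_um` | 3.5 (2.5 for T4) | µm | colocalization distance cutoff, strict |
| `contrast` | 0.5 | — | Michelson contrast of flashes vs gray |

The responder criterion (largest absolute averaged response exceeding
`k` baseline SDs, `k = 3`) is this package's interpretation: the source
procedure names responder selection but not its rule. Both the threshold
and the windows are configuration, and the flag is reported per ROI so
any other rule can be applied downstream.

## Colocalization counting

Inversion efficiency is the percentage of driver-labelled (channel A)
cell bodies with a reporter-positive (channel B) partner closer than the
threshold ("less than" is strict, per the stated cutoff). Matching is
one-to-one, built greedily by ascending pair distance with deterministic
tie-breaks (lower A index, then lower B index), which prevents one B spot
from validating several A spots. Greedy matching is not guaranteed to
reach the maximum-cardinality matching on arbitrarily dense clouds — on
uniform random 8+8-spot clouds with a threshold comparable to the cloud
size it falls short on roughly 9% of instances — but on cell-body-like
instances (spot spacing large relative to the threshold, planted partners
displaced by much less than the threshold) it agreed with an exhaustive
maximum-matching oracle on every instance tested, and that is the regime
the method is used in. An `any_within` mode (count every A with at least
one B inside the threshold) is provided for sensitivity analysis.
Specimen summaries average specimen-level percentages, not pooled cells;
a single specimen reports SEM 0 with an explicit flag. Manual post-hoc
spot corrections are out of scope.

## Genetics statistics

* `expected_survival()` enumerates the four equiprobable zygote classes
  of a two-heterozygote cross, removes lethal classes (the balancer
  homozygote is lethal by default), and returns the scored class's
  frequency among survivors — 1/3 for the standard balancer
  complementation cross.
* `one_proportion_ztest()` is the two-sided normal-approximation test
  without continuity correction (the convention named by the procedure);
  `one_proportion_exact()` offers the exact-binomial cross-check.
* `fisher_exact_2x2()` uses the probability-mass two-tailed rule (sum of
  hypergeometric probabilities at most that of the observed table).
* `delta_delta_ct()` averages technical replicates per biological
  replicate, forms per-replicate $\Delta Ct = Ct_\text{target} -
  Ct_\text{reference}$, and reports
  $100 \cdot 2^{\,\overline{\Delta Ct}_{ND} - \overline{\Delta Ct}_{D}}$,
  assuming ideal doubling (base 2) exactly as the quantification formula
  states; measured primer efficiencies are metadata and are not used as a
  correction. Significance is an unpaired two-sample t-test on the
  per-replicate delta-Ct values; per-replicate relative levels are
  reported normalized so the non-disrupting group mean is 100.
* t-tests are pooled-variance Student's tests by default (as named);
  Welch is available behind `var_equal = FALSE`. The display rule for
  imaging group comparisons shows asterisks only when the experimental
  genotype differs from both controls after Bonferroni correction, at the
  tier of the less significant adjusted p (cutoffs 0.05/0.01/0.001).

## The synthetic-data generator

The generator exists so that every stage can be tested by parameter
recovery. It emulates, with one named substream per independent source of
randomness fanned out from a single root seed:

* ROI fluorescence with a two-exponential bleaching envelope
  (fractional defaults $a_1 = 0.55$, $\tau_1 = 20$ s, $a_2 = 0.25$,
  $\tau_2 = 200$ s, offset 0.2, scale 1000 a.u.), GCaMP6f-like
  difference-of-exponentials transients (rise 0.05 s, decay 0.4 s,
  unit peak), onsets at nominal time + 6.25 ms + U[0, 8.33 ms), and
  additive Gaussian noise (Poisson optional). The default amplitude
  (peak deltaF/F 0.2) and noise SD (40 a.u.) put the per-frame SNR at 5,
  the regime the recovery and power tests are specified at. No published
  amplitude scale exists for raw fluorescence; these are free parameters
  and are documented as such.
* A genotype-by-compartment effect map whose default mirrors the
  qualitative disruption pattern (experimental multiplier 0.5 in the
  cell body and lobula arbors, 1 in M1/M8/M10, 3 in M5; controls 1
  everywhere). The map is fully configurable and no published effect
  size is hard-coded as truth.
* Movies as uniform disc blobs on a constant background — discs, not
  Gaussian profiles, so the masked pixel mean reproduces the generating
  trace exactly up to 16-bit quantization.
* 3D spot clouds with an exactly planted double-labelled fraction,
  partner displacement uniform within the jitter radius, and uniform
  decoys.
* Ct tables in which the disrupting sample's target Ct is raised by
  $-\log_2(\text{fraction})$ cycles with the reference gene shared, and
  multinomial cross counts over the enumerated surviving classes.

What it does **not** emulate: realistic optics (PSF, scanning artifacts),
motion beyond integer translation, neuropil contamination, biophysical
calcium dynamics, correlated or multiplicative noise, and plate effects
beyond an additive per-run Ct offset. Passing recovery tests therefore
demonstrates correctness of the analysis given the assumed signal model,
not robustness to every failure mode of real microscopy data.

## Numerical choices

* **Bleach fit**: Levenberg-Marquardt (`minpack.lm::nls.lm`) on a
  deterministic multistart grid (time constants at {0.02, 0.1, 0.3} and
  {0.5, 1, 3} of the fitted span; amplitudes from the first/last fitted
  values). The model is parameterized around the first fitted frame so
  that fast components remain well-scaled when the fitting window starts
  late in the recording. Amplitudes and offset are constrained
  non-negative — a bleaching envelope decays toward a non-negative
  plateau — which guarantees a positive baseline wherever it divides the
  trace; among converged fits, candidates with an everywhere-positive,
  finite baseline are preferred, then the lowest SSE wins. A constant
  trace collapses to its offset. Components are reported fast-first
  ($\tau_1 \le \tau_2$).
* **Moving average**: windows are centered on the grid point and
  half-open, $[t_k - w/2,\, t_k + w/2)$, so every sample belongs to
  exactly $\lceil w/s \rceil$ bins away from alignment pathologies and
  peak timing is not shifted. Empty bins are dropped; bins with one
  sample report SEM `NA`.
* **Matching tie-breaks**: equal distances resolve by lower A index,
  then lower B index, making results order-independent and reproducible.
* **Degenerate inputs**: identical constant delta-Ct groups return
  t-test p = 1 (equal means) or p = 0 (different means) rather than
  erroring; an all-identical ANOVA returns F = 0, p = 1; a single
  colocalization specimen reports SEM 0 with a flag.

## Problem sizes used by the test suite

The packaged tests run the pipeline at desk scale, chosen to exercise the
study's conditions while keeping the suite fast: full-length traces
(111 flash cycles, ~170 s at 38.9 Hz) for bleach-parameter and
peak-amplitude recovery (100 ROIs at SNR 5, median relative peak error
required ≤ 10%); 16-cycle traces at 50 ROIs per genotype for the
detection-power simulation (12 seeds, detection required in ≥ 90%);
500 null repetitions for the display-rule calibration (required ≤ 5%);
150 generator-drawn instances of ≤ 8+8 spots against the exhaustive
matching oracle; and 100 random instances against the brute-force
pooled-window oracle.

## Known limitations

Registration is integer-translation only. The responder rule and
response-window extents are interpretations, configurable but defaulted.
Greedy matching is a heuristic on dense clouds (see above). SEM in group
traces is across ROIs by default; per-fly aggregation must be done by the
caller from the per-ROI tables. The delta-delta-Ct quantification assumes
ideal primer efficiency exactly as its formula does.
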