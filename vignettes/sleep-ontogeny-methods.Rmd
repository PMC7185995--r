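---
title: "Methods: sleep ontogeny scoring, simulation and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep ontogeny scoring, simulation and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontosleep)
```

This vignette is the package's account of its models and the design
choices behind them. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Sleep scoring

Fly sleep is defined behaviourally: five or more consecutive minutes
without beam-break activity. `detect_sleep_bouts()` takes this literally —
a sleep bout is a maximal run of minutes with count exactly 0 and length
at least 5. There is no smoothing and no movement threshold: DAM counts
are 1-minute beam-break bins, so "inactive" means count 0, and scoring is
by construction invariant to rescaling nonzero counts.

Three choices matter at boundaries:

* **Continuous scoring.** Bouts are detected on the whole recording, not
  per-day slices, so a bout spanning midnight-ZT0 is one bout. Minutes are
  then assigned to each minute's own day, and a bout is *counted* (for
  bout-number and bout-length metrics) once, on its day and phase of
  onset.
* **ZT12-spanning bouts** contribute their minutes to both day and night
  sleep but are counted once, in the phase of onset. This keeps
  day + night = total sleep exactly while never double-counting a bout.
  The alternative (assigning all minutes to the onset phase) breaks the
  phase partition of minutes; the convention here preserves it.
* **Missing minutes** (invalid monitor status) break runs: a bout can
  never span a gap, which is the conservative reading of a recording
  artefact.

`align_to_zt()` trims a recording to whole experimental days starting at
the first ZT0 *strictly after* the recording start. A recording that
begins exactly at ZT0 therefore discards that first day. Screens load
flies mid-day and discard everything before the first full post-loading
day (flies need >16 h to recover from CO2 anaesthesia); the strict rule
reproduces that hygiene uniformly.

Dead flies are flagged by terminal inactivity: zero counts from some
minute through the end of the recording, for at least 12 h by default.
The window is configurable and the exclusion is always reported, never
silent.

## The ontogeny ratio and hit calling

Young (day 1) and mature (day 4–5) flies are different individuals, so a
per-fly ratio is impossible; the ontogeny ratio is the ratio of group
means of per-fly daytime sleep. Per-fly values default to the first full
recorded day (`use_days = 1` in `score_screen()`); averaging over more
days is a config choice, exposed because published screens do not always
state which convention they used.

The hit cutoff (default 1.2) is inclusive — "1.2 and below" — and
genotypes need at least 8 flies per age group to be called. A mature
group with zero mean sleep makes the ratio undefined: such a genotype is
a viability or assay failure, not an ontogeny hit, so it is excluded from
ranking but reported with its reason.

## Statistics

The screen's statistical toolkit is deliberately small:

* **Holm–Šidák corrected t tests** for families of two-group contrasts.
  The step-down adjustment is the closed form
  $\tilde p_{(i)} = \max_{j \le i}\, 1 - (1 - p_{(j)})^{m - j + 1}$,
  capped at 1. The two-sample t statistics (Student by default, Welch
  optionally) are computed from the closed forms so that `stats::t.test`
  remains an independent cross-check in the tests.
* **Welch's t test** (Welch–Satterthwaite degrees of freedom) for
  standalone two-group contrasts.
* **One-way ANOVA with Tukey HSD** for three or more groups. The F test
  comes from `stats::oneway.test(var.equal = TRUE)`; Tukey p-values use
  `stats::ptukey` on the Tukey–Kramer standard error, cross-checked in
  tests against `TukeyHSD` to 1e-8.

Degenerate inputs follow an explicit convention: two zero-variance groups
with equal means give p = 1, with unequal means an infinite statistic and
p = 0; both are flagged. All tests are two-tailed with α = 0.05 by
default.

The modifier-screen rescue rule is: the modified genotype's ratio exceeds
the base genotype's ratio *and* its young-vs-mature Welch contrast is
significant. Undefined ratios propagate as flags and never produce a
rescue call.

## FFT rhythmicity

Commercial actogram software reports an "FFT value" whose normalisation
is proprietary. This package defines the statistic explicitly:
the per-minute series is summed into 30-min bins (binning is configurable
down to 1 min; 30 min suppresses shot noise at no cost to circadian
resolution), mean-subtracted, and Fourier-transformed without
zero-padding, so the frequency grid is fixed by the window length.
Relative power at a period is the squared magnitude of its bin pair
divided by the total non-DC squared magnitude; the FFT value is the
maximum relative power over periods in 18–30 h. The statistic is
invariant to offsets and positive rescaling, and relative power sums
to 1.

The rhythmicity threshold (default 0.04) is an operating point of this
package, not a published constant: for a 7-day window the circadian band
holds 4 of ~168 frequency bins, and white noise exceeds 0.04 in well
under 5% of runs, while simulated rhythmic flies score an order of
magnitude above it. No quantitative match to any published FFT table is
claimed.

## Imaging quantification

* **Connectivity** for 3D components is 26-neighbour (the common 3D
  object-counter behaviour), with 6-neighbour available. The labelling is
  a breadth-first search over supra-threshold voxels, written in-package
  because no installed labeller handles 3D arrays.
* **Thresholds and size gates are inclusive**: at the published settings
  (threshold 52, sizes 2–80) a voxel of exactly 52 and components of
  exactly 2 or 80 voxels count.
* **ROI volume** follows the published volume settings (threshold 1,
  minimum size 1): the number of ROI voxels with intensity ≥ 1.
* **ROIs are supplied as masks**, matching assays where the region was
  selected manually; automatic segmentation is out of scope.
* Intensities are compared raw — constant acquisition and threshold
  settings across a comparison set are assumed, as they must be for any
  thresholded density to be comparable.
* The binary presence/absence criterion behind cohort innervation
  percentages is not stated in published work; `innervation_presence()`
  therefore takes `min_fraction` as an explicit, labelled assumption and
  attaches a Clopper–Pearson 95% CI to the cohort percentage.
* The intensity threshold for innervation *density* is dataset-specific
  (published analyses state only that settings were constant); it must be
  calibrated per dataset and passed explicitly.

CTCF is plain arithmetic — integrated density − area × mean background —
and may legitimately be negative (a cell dimmer than the background
estimate); it is reported as-is.

## Omics set logic

DE selection uses strict inequalities (`padj < 0.05`, `|log2FC| > 1.0`),
so boundary genes are excluded. Two published threshold conventions for
the same analysis differ (|log2FC| > 1.0 in the formal methods
definition; linear fold change > 1.2 in the results text); both ship as
presets and `methods` is the default because it is the formal definition.
The discrepancy is surfaced, not resolved.

Peak-to-gene ranking reduces each gene to its best peak (smallest
p-value, ties by larger signal), then ranks genes by p-value, signal, and
finally gene id, making the ordering total and the top-200 selection
deterministic under row shuffling. Whether published top-200 lists
deduplicated genes before or after cutting at 200 peaks is unstated; this
package returns 200 *unique genes* and documents that choice.

## The synthetic-data generator

The behavioural generator is a **semi-Markov alternating-renewal model**:
sleep and wake bouts alternate with lengths drawn per age and phase. Bout
lengths — the key architecture metric — are therefore parameterised
directly rather than emerging from a per-minute Markov chain:

* sleep bouts: 5 + geometric (every latent bout is detectable by the
  5-min rule),
* wake bouts: 1 + geometric,
* phase switch at ZT12; each phase segment is simulated with a 720-min
  stationary burn-in that is discarded, so the occupied fraction carries
  no start-up bias.

Because the stationary sleep fraction of an alternating-renewal process
is $m_s / (m_s + m_w)$, expected daytime sleep is set analytically:
given a target ontogeny ratio and a mature day-sleep level, the wake-bout
means are solved so the expected ratio equals the target by construction
(verified to within 2% over hundreds of flies in the tests).

Waking activity is Poisson (2 counts/min by default) with an optional
sinusoidal circadian modulation (period 24 h, amplitude 0.5); zero-count
waking minutes are re-drawn to 1 with probability 0.75 so wake is rarely
mis-scored as sleep. Scored sleep therefore slightly *exceeds* latent
sleep (residual zero-count wake minutes adjoining bouts), a bias of a few
percent that the calibration tests bound. An "arrhythmic" genotype pools
day and night bout parameters and removes the rate modulation; a
fragmentation factor < 1 shortens all bouts while leaving expected sleep
fractions — and hence the ratio — unchanged, mirroring the dissociation
between sleep architecture and sleep ontogeny that motivates keeping the
two parameter groups separate.

Wild-type defaults, chosen once as the study conditions: mature daytime
sleep 300/720 min, target ratio 1.75 (mid wild-type band, young flies
sleeping about twice the mature daytime amount), young day sleep-bout
mean 36 min versus mature 14 min (the juvenile day-sleep surplus is
carried by longer bouts), night sleep 612/576 min (young/mature).

The image generator grows disjoint connected blobs (6-connected growth,
so each blob is one 26-connected component) separated by at least one
voxel in the 26-neighbour sense, over background noise *clamped below the
detection threshold* (max 40 against threshold 52). That clamp is a
generator contract: it is what makes planted-truth recovery exact rather
than probabilistic. The omics generator plants DE memberships and
top-peak sets with strict margins around every threshold.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sleep latency and homeostatic rebound
structure, within-fly day-to-day correlation, monitor artefacts beyond
missing-status minutes, optical blur and anisotropic PSFs in image
stacks, correlated noise between channels, and p-value miscalibration in
real DE tables. The generator validates the *pipeline arithmetic*, not
the biology.

## Problem sizes and numerical choices

The test suite runs the property checks at these sizes, chosen to make
Monte-Carlo margins comfortable at interactive runtimes: 1,000 random
two-day traces against the brute-force bout scanner; 100 replicate
calibration screens at 32 flies/age; 5 replicate 50-genotype screens at
16 flies/group for hit sensitivity/specificity; 10,000 global-null
replicates (m = 6, n = 8) for the family-wise error; 1,000 Poisson-noise
periodograms; 100 random planted image stacks; 100 random datasets for
the Welch/Tukey cross-checks. Floating-point tolerances: 1e-12 against
the Holm–Šidák closed form, 1e-8 against the t/Tukey reference
implementations, exactness for bout detection, DAM round trips, puncta
recovery and set logic.

## Known limitations

* The DAM reader supports the 42-field, 1-minute dialect only (no 30-s or
  cross-beam variants, no hardware-artefact repair).
* The FFT value is this package's definition; absolute values are not
  comparable to proprietary software output, only within-analysis.
* Ratio-of-means ignores within-group variance; hit calling near the
  cutoff is noise-limited by group size, which is why the minimum-n
  filter exists.
* 3D labelling is pure R and sized for screening ROIs (tens of thousands
  of supra-threshold voxels), not whole-brain volumes.
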