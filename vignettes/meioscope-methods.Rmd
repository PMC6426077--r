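---
title: "Models and methods behind meioscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind meioscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioscope)
```

# Overview

`meioscope` scores meiotic chromosome-segregation phenotypes from
multichannel time-lapse z-stacks and validates every measurement against
simulated ground truth. This vignette is the package's account of the
models, the tunable parameters, and the design choices made where the
design was genuinely open.

# The segregation model

Each simulated cell carries one tracked chromosome (a heterozygous
GFP-marked centromere, i.e. two tagged sister chromatids) through meiosis I
and, where it occurs, meiosis II. A genotype is a small parameter set
(`genotype_params()`):

| parameter | meaning | default |
|---|---|---|
| `p_monoorient` | probability that sister kinetochores co-orient in MI | 1 |
| `forced_biorientation` | monopolin loss: sisters attach to opposite poles with probability 1 | `FALSE` |
| `protection_on` | pericentromeric cohesin survives anaphase I | `TRUE` |
| `cleavage_on` | separase cleavage competent | `TRUE` |
| `second_division_on` | meiosis II occurs | `TRUE` |
| `p_missegregate_mii` | per sister pair, probability of MII co-segregation | 0 |
| `p_transient_cohesion` | bi-oriented, unprotected cells that still stay in close proximity | 0 |

Rules, per cell: with probability `p_monoorient` the sisters co-orient (a
single marker focus in anaphase I); otherwise each sister attaches
independently and uniformly at random to one of the two poles, which
bi-orients exactly half of such cells in expectation — the simplest
mechanism consistent with the observed one-half bi-orientation of
Spo13-deficient cells, and deliberately free of extra parameters.
Bi-oriented sisters split `> 2 µm` (`SPLIT_FAR`) only when cohesin is both
cleavable and unprotected; protected or cleavage-dead cells split at most
`< 2 µm` (`SPLIT_CLOSE`). The cohesin pattern at anaphase I is deterministic
given the genotype: `PERICENTROMERIC` when protection and cleavage are both
intact, `RETAINED_EVERYWHERE` whenever cleavage fails, `ABSENT` when
cleavage proceeds without protection.

Choices worth recording:

- Monopolin loss (`mam1`) is modelled as *forced* bi-orientation, distinct
  from the randomized attachment of Spo13 loss, because cells lacking Mam1
  bi-orient almost exclusively rather than half the time.
- `p_transient_cohesion` defaults to 0 and is set to 0.1 only in the
  `spo13d_mam1d` preset. A global non-zero value would contradict the
  observation that essentially *all* bi-oriented Spo13-deficient cells
  split far; the double mutant's small close-proximity fraction is reported
  qualitatively ("a small fraction"), so 0.1 is a documented knob, not a
  fitted constant, and nothing downstream is tuned to it.
- `mad2d` is wild-type-like with `p_missegregate_mii = 0.05`, a modest rate
  mirroring its modest missegregation phenotype; `spo13d_mad2d` uses 0.2.
  Neither rate is printed anywhere as a number; both are config knobs, and
  the simulator is not tuned to reproduce observed spore-distribution
  endpoints.
- Separase-dead presets (`esp1_2`, `spo13d_esp1_2`) set
  `second_division_on = FALSE`: without cleavage the divisions cannot
  complete, and those conditions are scored only through anaphase I.
- Reproducibility uses a counter-based substream scheme
  (`substream_seed()`: repeated Lehmer/MINSTD mixing of `(seed, index)`,
  exact in doubles), so per-cell draws are independent of evaluation order.

# The synthetic movie renderer

`render_movie()` converts simulated outcomes into T×Z×C×Y×X stacks plus
pixel-exact ground truth. Defaults emulate the targeted acquisition regime:
7 z-slices at 0.85 µm, one frame per 15 min, 0.107 µm pixels (a typical
100×/EMCCD scale — the true pixel pitch of any given instrument should be
supplied in `imaging_config()`). Channel 1 carries the green marker (cohesin,
centromere marker, or biosensor — one per experiment, as in the real
strains); channel 2 carries kinetochore foci *and* diffuse nuclear securin
(the two red markers genuinely share a channel); channel 3 carries
histone-labelled nuclear masses.

Foci are 2-D Gaussians (σ = 1.3 px) per z-slice with Gaussian axial
attenuation (σ = 0.8 µm for point-like foci, 2 µm for diffuse signal) and a
mildly widened in-plane σ off focus. A full 3-D PSF is deliberately not
modelled: all measurements operate on z-projections, so axial fidelity
would add cost without changing what the tests can show. Noise is
`Poisson(signal·gain)/gain + N(0, σ_read)`, rounded to integer counts
(camera bit depth and EM gain are not modelled beyond this generic
Poisson-Gaussian form). Securin drops to 5% of baseline at each cell's
onset frame (safely below the <10% ground-truth contract); onset frames are
jittered by 0–1 frames across cells. When a cleaved biosensor disperses,
the diffuse amplitude is set by photon conservation (focus peak ×
σ_psf²/σ_nucleus²), which is why a dispersed focus is genuinely dim rather
than an arbitrary faint blob.

Cells are laid out on a non-overlapping grid (overlapping/crowded cells,
photobleaching, and stage drift are out of scope). Default movies are 6
frames with onset at frame 3–4: two metaphase frames, the two-frame
anaphase-I scoring window, and late frames showing meiosis II products when
a second division occurs. Ground truth records per-cell onset, class,
pattern, spot positions and amplitudes, and per-spore nuclear-mass size
factors, joinable to measurements by `cell_id` and frame.

What the generator does *not* emulate — cell-to-cell focus drift,
out-of-focus cells, autofluorescence gradients, segmentation ambiguity from
touching cells — bounds what passing tests show about real data: they
validate the measurement and decision logic, not robustness to every
real-microscopy artefact.

# Measurement and calling

**Projection.** Maximum projection is the default (the common choice for
punctate signals; mean projection is retained as an option and recorded in
the output). Note one consequence used throughout: the maximum over 7 noisy
slices raises the effective background of a projection (median ≈ 114 counts
for a 100-count background at these noise settings) and gives it
heavier-than-Gaussian upper tails. All presence thresholds are therefore
defined relative to robust statistics *of the projection itself* (median
and MAD), never to the nominal camera background.

**Thresholding.** Yen's maximum-correlation criterion is evaluated at every
bin of a 256-bin histogram spanning the observed min–max (emulating the
8-bit setting of the original ImageJ workflow); ties break to the lowest
bin; foreground is strictly above threshold. Degenerate (single-bin)
histograms are an error, not a silent threshold.

**Spot detection.** 8-connected components of the supra-threshold mask;
intensity-weighted centroids (better sub-pixel accuracy than binary
centroids; whether the original plugin weighted intensities is unknown, so
the choice is recorded here). `detect_spots()` defaults to `min_area = 2`
(suppressing single-pixel noise). The phenotyping layer passes
`min_area = 4`: a genuine diffraction-limited focus at σ ≈ 1.3 px covers
well over 4 supra-threshold pixels, while the max-projection noise tail
produces occasional 2–3-pixel false components. Both defaults are
configurable.

**Coordinates and distances.** Pixel coordinates are 1-based `(y = row,
x = col)` — the native convention of R matrices — and all reported distances
are in µm, computed in the projected 2-D plane.

**Onset.** Anaphase onset is the first frame whose background-subtracted
securin trace falls below 50% of the median of all preceding frames and
stays there for 2 consecutive frames. The 50%/2-frame rule is an
operational definition of a degradation that is judged by eye in manual
scoring; it is scale-invariant and ignores single-frame dips. The scoring
window is the frames within 30 min of onset — two timepoints at the default
15-min interval.

**Cohesin pattern.** Per window frame, with background statistics from the
crop's border ring (robust even when signal fills the interior):
chromatin-wide green area above `median + 3·MAD` exceeding 3 µm² ⇒
`RETAINED_EVERYWHERE`; otherwise a compact green focus within 0.75 µm of
the segment joining the two brightest kinetochore foci ⇒ `PERICENTROMERIC`
(pericentromeric cohesin sits at, or between, the kinetochores); otherwise
`ABSENT`. The quantitative value reported alongside is the mean of the two
brightest peaks of the green line profile between the kinetochores (line
mode, used for bi-orienting cells where cohesin lies between the
kinetochores) or the mean green intensity over the red footprints (dot
mode, the co-localization measure); the paper-style binary "pericentromeric
cohesin present" score is visual in origin, and this k·σ/geometry rule is a
stated surrogate for it, not a reconstruction.

**Distance class.** One green focus ⇒ `SINGLE_FOCUS`; two foci with maximum
window separation ≤ 2 µm ⇒ `SPLIT_CLOSE`, > 2 µm ⇒ `SPLIT_FAR`. Exactly
2.0 µm is assigned to `SPLIT_CLOSE`; any convention is defensible, one must
be fixed, and this closed upper bound is it. More than two foci is an
`NA` with a flag rather than a guess.

**Divisions and area ratio.** Two divisions require ≥ 4 final-frame
kinetochore foci (3 is flagged ambiguous); the nuclear area ratio keeps the
expected number of largest Yen-thresholded histone components and errors —
rather than improvising — when fewer are present.

# Statistics

Pairwise comparisons are Welch two-sample t-tests (two-sided; legends do
not specify sidedness, and two-sided is conservative), implemented on top
of `stats::t.test(var.equal = FALSE)` with an explicit zero-variance guard
(t = 0, p = 1 for equal constant samples). Raw p-values are reported
without multiple-testing correction, matching the annotation convention
(`***` p < 0.001, `**` p < 0.01, `n.s.`); error bars are SEMs. Tests are
run on per-cell intensities at n = 50 cells per genotype, the scale implied
by measuring 50 cells per condition.

Calibration experiments (`welch_null_calibration()`,
`protection_effect_power()`) render each cell in its own crop with its own
Yen threshold — exactly how the pipeline treats cell regions. This detail
matters: thresholding many cells with one shared data-dependent threshold
couples their measurement errors between images and destroys type-I
calibration, whereas per-cell thresholds keep errors independent. The
measured null rejection rate at α = 0.05 sits near nominal, and the
protection-on vs protection-off contrast at n = 50 yields p < 0.001
essentially always.

# Problem sizes and numerical choices

Default validation sizes, chosen as the package's own test conditions:
10,000 simulated cells for closed-form comparisons of the segregation
model; 50 rendered cells per genotype and marker (the scored population
size) for end-to-end recovery across all eight presets; 1,000 seeded
comparisons for null calibration; 40 seeded runs for power. 16-bit TIFF
I/O is exact for integer stacks (noisy renders are integral counts);
noiseless renders are kept in memory for exact photometric tests.
Degenerate inputs (constant images, coincident profile endpoints,
single-bin histograms, empty populations) raise errors rather than
returning conventional values, except where a convention is scientifically
standard (two-peak fallback on single-peak profiles, which is flagged in
the record).

# Known limitations

- The phenotype caller assumes one cell per supplied region; touching or
  overlapping cells are out of scope.
- Focus linking across frames is nearest-centroid within the scoring
  window; long-range tracking is not attempted.
- The simulator's categorical rules do not model recombination, chromosome
  arms, kinetochore–microtubule dynamics, or spindle mechanics; its
  frequencies are surrogates for scored outcomes, not mechanistic
  predictions.
- Real-data robustness (drift, debris, uneven illumination) is untested by
  construction; the synthetic generator is intentionally clean apart from
  Poisson-Gaussian noise.
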