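---
title: "Models and design choices in stopchange"
author: "stopchange maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in stopchange}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the generative models, the estimators, the
numerical conventions and the genuinely open design choices behind the
package. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The task model

One session consists of GO trials (70%) and STOP-CHANGE (SC) trials (30%,
split evenly between SCD 0 and SCD 300). Schedules are built by
largest-remainder apportionment of the configured fractions, so the
per-type count never deviates from the ideal by more than one trial; at
the human trial count of 864, the 15% cells are 129.6 trials, and the tie
between the two SC conditions is broken in listed order (SCD 0 gets 130,
SCD 300 gets 129). The order is a seeded uniform shuffle with CHANGE
targets balanced within each SC condition.

The stop-signal delay (SSD) is governed by a symmetric 1-up/1-down
staircase with a 50 ms step, clamped to `[ssd_min, ssd_max]`. Such a
staircase converges to the SSD at which the success probability of its
criterion is 50%, which is what licenses the mean-method SSRT. Two
success criteria are supported and attached to the presets:
`inhibit_only` for the pigeon variant (a withheld GO response counts) and
`inhibit_and_change` for the human variant (a correct CHANGE response
within the window is also required). Both are configurable because the
two variants of the protocol describe the criterion differently; the
package asserts neither as the only valid reading.

Unstated protocol constants had to be fixed once: the human SSD starts at
250 ms (only the pigeon start of 450 ms is documented), the staircase
clamps to `[0, go_response_window]`, and the pigeon response window is
set to 5000 ms (the scale of the intertrial interval; pigeons respond far
faster in practice, so the value only bounds omissions). GO omissions are
logged and excluded from GO-RT means.

## The generative agent

A `RaceAgent` implements the independent race model: an ex-Gaussian GO
process (parameters `go_mu`, `go_sigma`, `go_tau`; all ms) races a normal
stopping latency (`stop_mean`, `stop_sd`, truncated at 0) and the GO
response is emitted iff `GO RT < SSD + stop latency`. Independence of the
two processes is the standard assumption under which the mean-method
SSRT is consistent. The ex-Gaussian is the standard right-skewed RT
family; the published data report only condition means, so the
decomposition into `mu`/`sigma`/`tau` was chosen once: `tau = 80` ms and
`sigma` of 60–80 ms, a mid-range skew for RT data. This choice matters
because the staircase converges to the *median* of `GO − stop`, while the
mean method subtracts means; the resulting bias grows with `tau` (about
9 ms at the default parameters, about 17 ms at `tau = 100`). The test
suite checks recovery of the generative stopping latency to within 15 ms
at these defaults.

When the GO response is withheld on an SC trial, the CHANGE response time
measured from CHANGE onset is

```
RT2 = max(0, D − SCD) + change base RT + noise
```

with `D = max(0, Normal(d_mean, d_sd))` the residual interference delay:
the time after CHANGE onset during which CHANGE processing cannot proceed
because the STOP process still occupies the shared response-selection
capacity. This single parameter is the minimal generative account of the
serial↔parallel continuum: `D = 0` gives identical RT2 across SCD
conditions (slope 0, fully serial — the STOP process is finished before
the CHANGE process starts), `D ≥ 300` gives slope −1 (fully parallel),
and intermediate values give `slope = −D/300`. `expectedSlope()` is the
closed form `−(E[max(0,D)] − E[max(0,D−300)])/300`, which is exact for
the truncation used in sampling. `D` is subject-constant by default
(`d_sd = 0`); between-trial variability is supported but not asserted,
since the underlying psychology could be either.

Measuring RT2 from CHANGE onset (not GO onset) is the only convention
under which both published qualitative limits are attainable — slope → 0
when the STOP process completes in time and slope → −1 under full
capacity sharing.

### Cohort presets

`pigeonCohortSpec()` and `humanCohortSpec()` encode the study conditions:
20 subjects per species, population means chosen so the implied measures
match the published group means (pigeon: GO 826 ms, stopping latency
216 ms, base CHANGE RT 975 ms, `D = 165` ms ⇒ slope −0.55; human: GO
507 ms, stop 240 ms, base CHANGE 693 ms, `D = 161` ms ⇒ slope −0.54),
and between-subject SDs equal to the published SEMs times √20 (e.g.
pigeon GO: 48 × √20 ≈ 215 ms; slope: 0.06 × √20 × 300 ≈ 80 ms on the D
scale). The RT2 trial noise (60–80 ms) and a 5% CHANGE error rate are
realistic fill-ins for quantities the summary statistics do not
constrain. These defaults are fixed once and are not tuning knobs.

What the generator emulates: per-trial GO RTs, the stopping race against
a staircase-adapted SSD, CHANGE RTs spanning the serial↔parallel
continuum, and between-subject heterogeneity on the printed scale. What
it does not emulate: learning and fatigue within or across sessions,
sequential dependencies between trials, RT outliers and anticipations,
or any strategic adjustment of the GO process after STOP trials. Passing
tests therefore demonstrate correctness of the estimators and pipeline
under the race model, not robustness of the paradigm to those real-data
phenomena.

## Behavioral estimators

`computeSSRT(mean_go, mean_ssd)` is the plain difference; a negative
value is flagged with a warning rather than an error, mirroring
data-quality practice. The mean SSD is taken over all SC trials after a
burn-in of the first 20 SC trials (configurable), because the early
trace still carries the start value rather than the 50% point; RT2 means
are unaffected by the burn-in. `computeSlope()` divides by
`SCD0 − SCD300` and uses only successful SC trials with a correct CHANGE
response, matching the stricter success definition; this is a choice the
protocol descriptions leave open. No RT trimming is applied beyond
omission handling. Because all subjects share the same SCD values, the
mean of per-subject slopes equals the slope of the per-condition grand
means exactly — the suite asserts this linearity identity, which is also
what makes published group means usable as exact oracles for the slope.

## Histology quantification

Synthetic sections are 8-bit grayscale images with dark elliptical
"nuclei" on a light noisy background (the polarity of DAB staining);
internally all computations run on the inverted stain channel
`255 − gray`. Planted cells carry an exact integer stain peak; background
noise (SD 4 by default) models staining variability. Cells are placed by
rejection sampling with a no-overlap constraint; densities near the
random-packing limit raise a generation error rather than degrading
silently. The default pixel size is 0.001 mm/px — at that scale the
default cell radii (≈4.5 px) correspond to ≈9 µm nuclei — and is
configurable because the true magnification calibration of an imaging
setup is rig-specific.

Threshold calibration mirrors practice on the control region CPi: the
lower threshold is the minimum stain intensity among weak exemplar
cells, the upper the maximum among intense ones, and the band is then
frozen for every image of the run. Detection binarises the stain channel
inside the inclusive band, labels 8-connected components, and applies
the standard particle filters as strict inequalities: area > 15 px and
roundness > 0.40. Roundness follows the ImageJ convention
`4·area/(π·major²)` with the equal-area moment ellipse, which reduces to
`sqrt(λ_minor/λ_major)` of the second-moment matrix; a 1/12 per-pixel
variance term is added so one-pixel-wide components get a finite minor
axis (a 1 × 40 px line scores ≈ 0.03, a radius-3 disc ≈ 0.95). A
particle counts toward an ROI if its *centroid* lies inside the ROI
polygon (even-odd rule on pixel centers); the boundary rule is not
documented in the reference workflow, and the centroid rule is the least
surprising one. Counts are standardised to cells/mm² by
`n / (ROI pixels × pixel_size²)`, and aggregation takes arithmetic means
over slices within hemisphere (2 slices for CPi, 3 for NMm/NIML/MM),
then over hemispheres when pooling is enabled.

The component labelling is implemented as connected components of the
8-neighbour pixel graph (via igraph); the test suite checks it against
an independent flood-fill oracle on hundreds of random images.

## Inferential layer

t-tests delegate to `stats::t.test` (Student: pooled variance,
df = n₁+n₂−2; Welch: Satterthwaite df). The mixed-design
repeated-measures ANOVA is the classical univariate analysis via
`stats::aov` with an `Error(subject)` stratum: the between-group effect
is tested against subjects-within-groups, the within effect and the
interaction against the subject × within residual, giving the textbook
uncorrected dfs (e.g. (1, 38) for 2 conditions × 2 groups of 20;
(3, 51), (6, 51) and (2, 17) for 4 areas × groups of 6/6/8). Partial η²
is `SS_effect / (SS_effect + SS_error)` with each effect's own error
stratum. No sphericity correction is applied by default (uncorrected dfs
are the reporting convention this package mirrors); Greenhouse–Geisser
is available as an option, with ε computed from the pooled within-group
covariance. Pairwise group comparisons are Student t-tests per within
level with p-values multiplied by the number of pairs in the family and
capped at 1 (displayed "> 0.999" when capped). This is a simple-effects
formulation on the cell data; it uses per-cell error variances rather
than the pooled ANOVA error term some GUI packages use, a deliberate
robustness choice.

`spearmanTest` computes rho as the Pearson correlation of average ranks.
For n ≤ 9 without ties the two-sided p is exact by full enumeration of
the n! permutations (n = 8 at the study's group size takes well under a
second); otherwise the t-approximation is used. The exact path is
cross-checked against both a brute-force enumeration and the library
algorithm in the tests.

The Bayes factor for the absent interaction uses the BIC approximation
`BF01 = exp((BIC_alt − BIC_null)/2)` (unit-information prior), with the
two models fit by maximum likelihood as linear mixed models with a
random subject intercept, differing only in the interaction term. The
original analysis reports a Bayes factor without its computation method,
so this package implements and labels the BIC approximation; reproducing
the exact published value is explicitly not a goal.

## Orchestration

`runBehaviorExperiment()` and `runZenkExperiment()` run the full
synthetic experiments (behavior: 20 + 20 subjects; histology: groups of
6/6/8 with 4 areas × 2 hemispheres × 2–3 slices each) and are
deterministic given a master seed, which fans out to recorded
per-subject and per-section seeds so any unit can be re-simulated in
isolation. In the histology generator, each STOP-CHANGE subject's NIML
density is coupled to its simulated slope (default gain 1500 cells/mm²
per slope unit, with the residual SD chosen so the total between-subject
SD still matches the published SEM), emulating the finding that more
serial subjects show higher NIML activity; the other areas and groups
draw independently from the published means and SEMs. The hemisphere
pooling decision repeats the published logic: pool iff neither the
hemisphere main effect nor the hemisphere × area interaction is
significant at 0.05.

The pipeline is exposed as package functions plus this vignette rather
than a shell executable: the package's users work in R, and
`runBehaviorExperiment()` / `runZenkExperiment()` / `runReport()` are the
subcommands. Trial logs, subject/group tables and densities are written
as tidy CSV (17-significant-digit serialisation, so logs round-trip
losslessly) with seed and config-hash header comments; statistics go to
JSON.

### Problem sizes in the shipped checks

The unit tests run the experiments at reduced scale (4-subject cohorts,
120-trial sessions; histology groups of 2/2/3 with 128 px sections at
half density), sizes chosen to exercise every code path while keeping
the default suite quick; `scripts/acceptance.R` and the acceptance tests
use the full staircase length (2000 SC trials) and the full 20 + 20
behavioral design. The type-I-error check runs 2000 null replicates of
the 2 × 2 mixed design; the particle-counting oracle comparison runs 200
random 64 × 64 images.

## Known limitations

- The agent model is deliberately minimal: no trial-to-trial adaptation,
  no GO-process slowing after stop failures, no RT outlier process.
- The mean-method SSRT inherits its known skew bias (see above); the
  integration method is out of scope.
- Overlapping cells are not split (no watershed); the synthetic
  generator avoids overlap, so counting accuracy on real, touching
  nuclei will be lower than the synthetic sensitivity suggests.
- The exact Spearman path requires untied data; ties fall back to the
  t-approximation regardless of n.
- Pairwise comparisons use per-cell variances, so they will differ
  slightly from EMM-based contrasts computed from the pooled error term.
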