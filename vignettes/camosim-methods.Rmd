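---
title: "camosim: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{camosim: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

camosim is a headless toolbox for artificial camouflage evolution: a
real-coded genetic algorithm drives procedural animal- or egg-pattern
phenotypes through a simulated visual-search predation task, and camouflage
is quantified by CIELAB statistics and Gabor edge disruption. This vignette
is the package's own account of the science it implements: the models and
their assumptions, the parameters that matter, what the synthetic parts do
and do not emulate, and the choices made where the design was genuinely
open.

## The genetic algorithm

Populations hold `N` individuals (default 24 — small enough that one
observer can evaluate every member in a session before fatigue) whose
genomes are fixed-length vectors of decimal genes in [0, 1]. Each gene
carries a three-level tag (`group_subgroup_channel`, e.g. `col_mac_lum`)
that gives the genome functional structure without multiple chromosomes.

**Initialization.** The default starting population is *overdispersed*:
each gene position receives the values `k/(N+1)`, `k = 1..N`, independently
permuted across members. The initial genotypic space is then as wide as
possible for the population size, with no duplicated values and no genes on
the boundary. The diversity statistic used throughout (mean over gene
positions of the mean pairwise absolute difference) is exactly 1/3 for an
overdispersed population of any size, which is used as the reference level
`D0` for adaptive mutation. Uniform-random, Gaussian and custom-matrix
starts are also available.

**Selection and turnover.** After each predation round the population is
ranked by survival time (rank 1 = longest; ranking can be reversed to
select for conspicuousness). The bottom two thirds die; the top third
survives unaltered *and* breeds, in two rounds of fresh random pairing,
each breeder producing one offspring per round. Survivors are re-evaluated
every generation — detection times are noisy, so fitness is never carried
stale. Ties in fitness are broken deterministically in favor of the member
shown later in the session (a target found equally fast against a
less-fresh observer earned it). With an odd breeder count, the last breeder
draws a random second partner so the offspring count stays exact.

**Lifelines.** Ranking noise can delete genuinely good phenotypes. The top
`lifeline_count` (default 3) individuals of each generation are protected:
if the next ranking drops one into the deletion pool it is reinstated
unmutated, consuming one planned offspring slot; survivor rankings are not
re-adjusted.

**Crossover.** Genes are decimal, so copying whole parental values could
never produce intermediates (a "white" and a "black" parent could only make
white or black offspring). Offspring genes are therefore *randomly weighted
averages*: `g = w a + (1 - w) b` with an independent uniform weight per
position. Offspring are always contained in the per-gene parental interval,
and crossover alone contracts variance — mutation is what keeps the
population from fixating.

**Mutation.** Point mutation hits each gene independently (default rate
0.1) with magnitude `step * K`, `K ~ Poisson(1)` and an equiprobable sign
(default step 0.05); the Poisson mixture provides mostly-small steps with
occasional larger jumps. Out-of-range results are *reflected* back into
[0, 1] rather than clipped, so probability mass does not pile up at the
bounds. Tag-aware structural mutations — swap, scramble, and weighted
duplication — act only within *equivalence classes* of genes sharing group
and channel labels (e.g. maculation luminance onto background luminance),
so moved values keep their phenotypic meaning; each event has a low default
probability (0.02). Adaptive mutation
(`rate = base (1 + c_d (1 - D/D0)) (1 + c_f u)`, clamped to
[0.01, 0.5], with `u` the individual's relative unfitness) is implemented
but off by default: the source system describes it as an option that "can
be set", and the acceptance experiments run the plain defaults.

## Animal phenotypes

Maculation is sampled from a precomputed *gamut* of Gray-Scott
reaction-diffusion textures: one integration of

```
du/dt = Du lap(u) - u v^2 + F (1 - u)
dv/dt = Dv lap(v) + u v^2 - (F + k) v
```

on a grid where the feed rate `F` varies along x and the kill rate `k`
along y, so a single sheet spans spots, stripes and labyrinths. Constants
are the classic parameterization (`Du = 0.16`, `Dv = 0.08`, `dt = 1`,
`F` in [0.01, 0.09], `k` in [0.045, 0.070], 256x256, 5000 Euler steps), all
exposed in the config. The integrator uses zero-flux boundaries (periodic
wrapping would abut opposite parameter extremes) and raises an error naming
the offending `F, k` corner if the field diverges. The initial condition is
`u = 1, v = 0` plus a centred square of `u = 0.5, v = 0.25` with 5%
multiplicative noise *and* a sparse 1% scatter of `v = 0.25` dots: a single
centre seed leaves the outer sheet unpatterned at 5000 steps, and genes
address windows anywhere in the sheet. The gamut is built once per run,
cached in memory keyed by its full parameter set, and shared by all
genomes; genes select windows into it, which keeps rendering deterministic
and fast.

Rendering maps tagged genes onto: window position/size (window side 8-45%
of the sheet, times a 0.5-2x scale gene), stripe stretch (1-8x compression
of the source rows), a linear luminance gradient (angle and strength),
binarization threshold (maculation fraction is monotone non-increasing in
the threshold gene), optional bilateral mirroring, CIELAB coloration (six
genes mapped affinely onto the configured channel ranges; demo limits
L 0-100, A -60-60, B -10-70), edge enhancement, and speckling. Symmetry is
an experimenter setting, not a gene: target shape and symmetry define the
prey, the genome defines its coloration.

Edge enhancement raises luminance contrast at the maculation boundary —
dark side darker, light side lighter — with intensity (0-25 L), band width
(0-10 px, via an iterative-dilation distance band) and Gaussian falloff
sigma (0.5-3 px) independently gene-controlled per side. Speckling adds
salt noise (0-5% of pixels) blurred at 0.5-3 px onto the luminance plane;
it is applied last (the source figure does not fix the order), and its
noise stream is derived deterministically from the run seed and genome id,
so rendering is a pure function of (genome, spec, gamut, seed).

Because CIELAB colors are composed before any sRGB conversion, rendered
values always respect the configured limits; conversion to sRGB (D65,
standard transfer, via `grDevices::convertColor`) clips out-of-gamut pixels
per channel and reports the count.

## Egg phenotypes

Egg patterning is not reaction-diffusion mediated; the egg generator
instead thresholds a Gaussian noise sheet whose smoothing sigma varies
along y (so one axis of the window genes selects granularity), twice: two
maculation layers with independent windows, shading gradients, thresholds
(values below the threshold are zeroed, keeping graded deposition) and
deposition weights. The second layer is smeared by a seeded random walk
(0-40 steps of 1-5 px in 8-neighbour directions, union of pasted copies —
the area can only grow), producing streaks and spirals. The per-pixel
deposition field is the clamped sum of a base-deposition gene and both
weighted layers.

Coloration has two axes: *deposition* (pigment amount) and *ratio*
(biliverdin : protoporphyrin). Anchor CIELAB values (bare shell
L 93, A 2, B 12; full biliverdin 55, -18, 2; full protoporphyrin
35, 18, 30 — parametric stand-ins, user-configurable, since the underlying
empirical measurements are not printed in the source) are interpolated in
LCh space: the pigment color interpolates between the two pigment anchors
by ratio, and the output interpolates from shell toward pigment by
deposition. LCh interpolation is a deliberate choice: straight-line CIELAB
interpolation toward the biliverdin anchor lets chroma dip mid-path,
contradicting the model's premise that more pigment means darker *and more
saturated*; in LCh, lightness is monotone non-increasing and chroma
monotone non-decreasing in deposition by construction. The "avian bound" is
the reachable surface of the model itself (channel ranges over a fine
deposition-ratio grid). A final exposure-shift gene adds up to +/-15 L
units uniformly (gene 0.5 = no shift), emulating camera exposure variation
between background photography and egg colorimetry; 15 L is visible but
not dominant. The two layers share one ratio gene and differ in deposition
weights — the source does not specify whether layers carry separate
pigment identities, and a shared ratio with per-layer weights reproduces
the visible variation with two fewer genes.

## Camouflage metrics

For each placed target, the *local background* is a circle of diameter
twice the target's maximum diameter (convex-hull extent of the mask),
centred on the target centroid, target pixels excluded, clipped to the
slide with a flag. Channel means and population (divide-by-n) standard
deviations are measured for target and local background; the six
differences ΔμL, ΔμA, ΔμB, ΔσL, ΔσA, ΔσB are emitted as magnitudes by
default (the source archives them as declining magnitudes; signed values
are available via a flag).

*GabRat* measures edge disruption: for every outline pixel, a bank of four
evenly spaced Gabor quadrature pairs (sigma 3 px, wavelength 2 sigma,
zero-DC, envelope elongated 2:1 along the edge axis for orientation
selectivity) is evaluated; bank energies are interpolated periodically over
orientation at the local outline tangent ("true" edge) and at its
perpendicular ("false" edge), and GabRat is the mean of
`false / (false + true)` over the outline. The tangent is estimated from
the gradient of the Gaussian-smoothed mask (normal + 90 degrees) rather
than by ordering the boundary into a chain: at pixel scale the two agree to
a couple of degrees, and the gradient form is robust to masks whose
boundary is not a single simple curve. Pixels with no edge signal either
way score the neutral value 0.5 and are counted. The ratio is invariant to
affine rescaling of the plane (zero-DC kernels); A and B planes are
z-scored before filtering anyway so channel scale cannot dominate. The
whole-plane FFT filtering path and a naive per-pixel convolution path share
boundary semantics (circular) and agree to numerical precision; the naive
path exists purely as the oracle route.

## The simulated observer

The human player is replaced by a parametric observer. A conspicuousness
score `c = w_mu |dmu| + w_sd |dsd| - w_gab mean(GabRat)` (differences
normalized by the configured channel ranges) sets the median of a
log-normal detection-time distribution, `median = baseline exp(-c)`
(baseline 9000 ms), optionally shrunk per completed slide by a
search-image learning factor and truncated at the 15 s slide timeout;
a lapse probability produces outright misses. Click execution adds a
gamma-distributed delay with median about 300 ms, which is what makes the
hybrid fitness rule meaningful: *survival time* is the response time unless
capture minus response exceeds 600 ms, in which case the capture time is
used — a long move-to-click gap implies the initial movement was not a
true detection. Timeouts score the full 15000 ms.

What the observer does and does not emulate: it reproduces the timing
semantics (response vs capture, timeout, warm-up slides, per-slide
learning) and a monotone link from camouflage metrics to detection time;
it does not model saccadic search, peripheral acuity, or inter-observer
variation beyond its noise and lapse parameters. A green directional-
evolution test therefore establishes that the GA optimizes whatever the
observer can see — not that the evolved patterns would deceive a human.

Slides are centre crops (default 1478 x 1130 px) of the assigned
backgrounds with one target placed per slide, uniformly rotated and
positioned so the rotated raster lies fully inside the crop; a random
display sequence without replacement covers all N targets, preceded by two
randomly generated warm-up targets that absorb the strong first-slide
effect and are excluded from ranking. Background assignment is
re-randomized each generation (the source does not fix target-background
pairing; re-randomizing avoids overfitting a member to one image).

## Synthetic backgrounds

The fixture generator produces spatially correlated CIELAB noise:
per-channel Gaussian-filtered white noise restandardized to requested
means and SDs, with blur sigma set to half the requested autocorrelation
length (blurred white noise has Gaussian autocovariance
`exp(-d^2/(4 sigma^2))`, so the 1/e length equals `2 sigma`). This
emulates the first- and second-order statistics and correlation length of
habitat photographs; it does not emulate oriented structure, object
boundaries, lighting gradients or multi-scale clutter, so synthetic-
background results speak to color/luminance matching, not to disruption
against structured scenes.

## Numerical choices and degenerate inputs

* Gene bounds are enforced after every operator; point mutation reflects,
  colorize clamps at the configured limits, deposition clamps to [0, 1].
* A flat reaction-diffusion field (no initial perturbation, or a
  degenerate window) min-max normalizes to all zeros and is flagged rather
  than erroring; binarization of a flat patch yields all-or-nothing
  maculation, which is a legitimate plain phenotype.
* `local_region` errors when the target fills its sampling circle; GabRat
  errors on a mask with no outline and scores 0.5 (flagged) where there is
  no edge signal either way.
* Chromosome logs store genes at 6 decimal places; round-tripping is exact
  at that precision and is what "bit-identical logs" means across runs.
* All stochastic draws flow through R's global RNG seeded once per run;
  seeded sub-streams (gamut build, backgrounds, per-genome speckle and
  walks) are derived deterministically from the run seed and a string key,
  and evaluated under save/restore so they do not perturb the main stream.

## Known limitations

* The hidden-optimum benchmark converges steadily under the stated default
  operators (rate 0.1, step 0.05) but reaches a best-individual mean gene
  error of about 0.06-0.07 at generation 30 (0.02-0.03 by generation
  50-60): averaging crossover collapses diversity within about ten
  generations and progress is then mutation-limited. The package reports
  this honestly rather than retuning the published defaults.
* GabRat values depend on the ratio of target size to filter sigma; for
  targets whose radius is comparable to the kernel half-width the
  parallel/orthogonal distinction blurs and values drift toward 0.5.
* The egg color model is parametric, not fitted to measured egg spectra;
  anchors are configurable for users with calibrated data.
* Multiple-targets-per-slide (2-6) and the location-click fitness method
  are implemented only in their single-target/trivial forms.
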