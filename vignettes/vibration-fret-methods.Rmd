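---
title: "Methods: calcium response classification under localized substrate vibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calcium response classification under localized substrate vibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechfret)
```

## The experiment mechfret models

A glass micro-probe (tip diameter about 50 µm) is inserted into a soft
polyacrylamide gel about 13 µm away from the edge of an adherent cell
(typical diameter 125 µm). A spring-loaded collision sets the probe tip
oscillating at about 140 Hz with a zero-to-peak excursion of about 70 µm,
which shakes the substrate under the cell. The cell expresses a
FRET-based calcium biosensor; donor (ECFP) and acceptor (YPet) emissions
are imaged in time lapse, and the acceptor/donor ratio reports the
intracellular calcium concentration. Two quantities are analyzed:

1. the **calcium response** of each stimulated cell, classified as
   *global* (cell-wide ratio rise), *local* (rise confined near the
   probe), or *none* (sub-threshold change), with per-condition response
   probabilities compared by an exact contingency-table test; and
2. the **substrate deformation**, measured by tracking fluorescent
   fiducial beads embedded at the gel surface between a resting and a
   displaced frame, from which displacement and strain maps are computed.

No public imaging data accompany this kind of experiment, so the package
ships a synthetic generator that emulates all inputs with known ground
truth. Every analysis operation is exercised end to end against that
ground truth.

## Response classification

For each cell the pipeline (`run_cell()`):

1. subtracts, per frame and channel, the mean intensity of a cell-free
   background region (negative results are clipped at 0 — the source
   protocol is silent on negative counts, and clipping keeps ratios
   stable at low intensities; the donor additionally must exceed
   `donor_floor` = 1 count for a pixel to contribute);
2. splits the cell mask into three bands of equal extent along the axis
   from the probe to the cell centroid (`partition_regions()`). The
   original protocol divided the cell "vertically" because the probe sat
   below the cell in the camera frame; using the probe axis generalizes
   this to arbitrary probe placement and reduces to the vertical split in
   the original geometry. Ties at band boundaries go to the band nearer
   the probe;
3. computes the band ratio per frame by dividing the average acceptor
   intensity by the average donor intensity over the band
   (`region_mean_ratio()`), matching how region ratios are formed in
   ratiometric practice; the pixel-wise ratio map
   (`compute_ratio_map()`) exists for display and per-pixel analysis;
4. takes the baseline as the pre-stimulus mean of each band (at least 3
   pre-stimulus frames required) and the stimulated increase as the
   baseline-normalized **peak** ratio within a 60 s post-stimulus window.
   The underlying protocol does not state the window length or whether
   peak or plateau was used; the time courses in this assay are clear
   transients, so the windowed peak is the natural summary, and 60 s
   comfortably covers the rise at the default kinetics (rise 3 s,
   recovery 20 s);
5. classifies with `classify_response()`, in rule order:
   - *none* if no band increase exceeds 10% of baseline — applied first,
     on the maximum band delta, because a cell with no band above
     threshold has no response to localize;
   - *global* if the farthest band's increase is at least half of the
     closest band's (a tie at exactly half counts as global — "at least
     half");
   - *local* otherwise.

   All deltas are relative (fractions of baseline): the 10% criterion is
   inherently relative, and using relative deltas in the global/local
   comparison keeps the two rules on one scale. The comparison is scale
   invariant, so only the none-threshold is an absolute choice.

## Substrate mechanics

`track_beads()` detects beads in the reference frame as local intensity
maxima and matches each in the displaced frame by normalized
cross-correlation over a search window, with parabolic sub-pixel
refinement of the correlation peak. Two numerical choices matter:

- the correlation window is **Gaussian-weighted** (`weight_sigma` = 2 px).
  The displacement field varies strongly across a flat 15 px window
  (strains of 30-40% near the probe), so neighboring beads inside the
  template otherwise average into the match and bias displacement extrema
  toward their surroundings by several percent. Center-weighting
  concentrates the match on the detected bead; measured on synthetic
  pairs it reduces the mean per-bead error from roughly 0.15 px to
  below 0.1 px.
- matches are screened by the **normalized-median test** (residual
  against the median displacement of the 8 nearest neighbors, tolerance
  2): with many similar spots, the globally best correlation is
  occasionally the wrong bead, and such vectors are far outside the
  locally smooth field.

`interpolate_field()` maps the scattered bead displacements onto a
regular grid (default spacing 2 µm) by piecewise-linear Delaunay
interpolation: it is exact for affine fields — which makes a clean
oracle — and leaves nodes outside the bead convex hull undefined.
For strain maps, `smoothing = "tps"` replaces the node values with a
penalized thin-plate regression spline fit (smoothness by GCV): the
sub-pixel tracking noise, differentiated across bead-to-bead baselines
of a few µm, would otherwise appear as spurious strain of a few percent.
The spline's penalty null space is affine, so affine fields are still
reproduced exactly. `cmd_strain()` reports displacement summaries from
the unsmoothed field (interpolation does not amplify noise) and strain
from the smoothed one (differentiation does).

`displacement_to_strain()` uses the stated finite-difference scheme —
central (3-point) differences at interior nodes and one-sided 2-point
differences at the boundaries — to form the normal strains
$E_x = \partial u_x / \partial x$ and $E_y = \partial u_y / \partial y$,
and the total strain $E = \sqrt{E_x^2 + E_y^2}$. The total-strain
formula is taken with normal components only; no shear or
large-deformation terms are included, matching how the quantity is
described in this assay ("the strain in x and y axis"). On smooth
fields the interior stencil error is $O(h^2)$, which the tests verify by
Richardson halving against the generator's closed-form gradient.

## Cohort statistics

Counts $(n_g, n_l, n_n)$ of the three classes in a condition are treated
as a multinomial sample of size $N$. `estimate_proportions()` returns
$\hat p_k = n_k/N$ with the marginal binomial standard deviation
$\sqrt{\hat p_k (1-\hat p_k)/N}$ — the standard estimator for one
component of a multinomial, and the only closed form consistent with
reporting a per-class standard deviation.

`fisher_exact()` tests independence of conditions and classes with both
margins fixed. All tables with the observed margins are enumerated
(recursively, row by row; a 2×3 table with a few hundred samples has at
most a few thousand compatible tables, so exhaustive enumeration is
cheap and exact) and the p-value sums the multivariate-hypergeometric
probabilities of tables no more probable than the observed one — the
two-sided Freeman-Halton convention used by mainstream implementations,
which reduces to the classic two-sided Fisher test for 2×2. Probability
comparisons carry a relative slack of 1e-12 so floating-point ties are
counted deterministically. Zero-margin rows or columns are dropped with
a warning before testing; `compare_conditions()` flags significance at
p < 0.05. No multiple-testing correction is applied (each treatment is
compared only against the control).

## The synthetic generator

The generator produces the three kinds of raw data the pipeline
consumes. Its defaults are the documented conditions of the emulated
experiment wherever those exist; the remaining values are chosen once as
typical of this kind of acquisition.

**Probe trace** — a damped sinusoid
$a(t) = A\,e^{-t/\tau}\sin(2\pi f t)$ with $f$ = 140 Hz and $A$ = 70 µm.
"Amplitude" is taken as zero-to-peak, matching the sinusoid
parameterization (the printed phrase does not distinguish zero-to-peak
from peak-to-peak). The envelope constant ($\tau$ = 0.1 s) emulates a
triggered, decaying collision-driven oscillation; `damping_time = Inf`
gives the sustained trace used for spectral characterization.

**Substrate field** — a phenomenological radial profile around the probe
edge: the displacement magnitude rises linearly from 60% of the peak at
the probe edge to the full peak (13.5 µm) at 13 µm from the edge, then
decays exponentially with a 30 µm length scale, directed along the
(horizontal) vibration axis. This is a descriptive fit to the measured
maps, not a mechanical gel model; with these values the maximum strain
inside a cell footprint placed at the working distance is about 0.4,
and the displacement at the far cell edge is below 2% of the peak. The
closed-form gradient is carried alongside every sampled field as the
strain oracle. Bead images place about 0.03 beads/µm² (a dense fiducial
layer, as 1 µm beads at high surface density) rendered as Gaussian spots
(sd 0.8 µm, peak 2000 counts over a 100-count background) with Poisson
noise; the displaced frame moves each bead by the field at its reference
position.

**FRET movies** — each phantom cell is a 125 µm disc with the probe
placed beyond its edge at the 13 µm working gap. The calcium signal is
separable, $c(x,t) = A(x)k(t)$: $A(x)$ decays exponentially with
distance from the stimulation-proximal cell edge (length scale infinite
for a global response, 25 µm for a local one, amplitude 0.4; a
non-responsive cell gets 0.03, below the classification threshold), and
$k(t)$ rises with a 3 s constant and recovers with a 20 s constant,
normalized to peak 1. The acceptor channel scales with $(1+c)$ and the
donor with $1/(1+c)$ — the monotone ratio response is all the pipeline
uses, and no spectral bleed-through or photophysics is modeled. Counts
(gain 800 per channel, resting ratio 1.2, background 100) receive
Poisson noise, giving a per-pixel ratio CV of about 5% — high enough
that classification is a real statistical task, low enough that band
means over hundreds of pixels are stable. Movies default to 56×56 px at
2.5 µm/px, 45 frames at 2 s intervals with stimulation at frame 10.

**Cohorts** — classes are drawn i.i.d. from $(p_g, p_l, p_n)$ (or fixed
as explicit labels for balanced designs); per-cell seeds are derived as
master seed + cell index, so any cell can be regenerated independently
and the whole bundle is byte-reproducible.

### What the generator does and does not emulate

The phantoms capture the statistical structure the pipeline depends on —
ratiometric channels with shot noise, background, a spatial response
gradient, band geometry, bead fields under a known displacement — but
not cell-shape irregularity, photobleaching, focus drift, motion
artifacts, spectral bleed-through, or biosensor saturation. Passing
tests therefore demonstrate the correctness of the computations and the
internal consistency of the pipeline, not robustness to every real-world
artifact of live-cell microscopy.

## Problem sizes and determinism

The shipped tests run the full chain at deliberately desk-friendly
sizes: 56×56 px movies, a 300-cell balanced cohort for end-to-end
classification, 160×160 px bead fields with ~300 usable beads, and
exhaustive exact-test verification for all 2×2 tables up to N = 30 and
all 2×3 tables up to N = 12 (with a seeded random sample of larger
margins) — the enumeration itself is exact at any N; the verification
grid is simply kept to sizes where the independent brute-force oracle is
also cheap. All stochastic stages take explicit integer seeds, and
every generator is bit-reproducible for a fixed seed.

## Known limitations

- The band partition assumes a single connected cell footprint and a
  probe outside it; degenerate masks (under 3 px extent along the probe
  axis) are rejected rather than guessed at.
- The strain field carries only the two normal components; shear is not
  estimated, so the total strain is a lower bound on a full tensor norm.
- Bead tracking assumes displacements within the search radius
  (±15 px by default) and a bead density at which spots remain
  resolvable; denser fields raise a warning.
- The recovered displacement maximum is read from beads near the peak
  ring, so it carries a small negative bias (about 1-2% at the default
  bead density) from finite sampling of a spatial maximum.
- The exact test enumerates tables with both margins fixed; for very
  large cohorts (N in the thousands) asymptotic tests would be cheaper,
  but cohort sizes in this assay are tens of cells.
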