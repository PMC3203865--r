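# mechfret

Analysis of intracellular calcium responses to localized mechanical
stimulation, for experiments in which a vibrating glass micro-probe
(~140 Hz, ~70 µm tip excursion) is inserted into a soft substrate gel
next to an adherent cell expressing a ratiometric FRET calcium biosensor
(donor ECFP, acceptor YPet). The package is aimed at mechanobiology labs
running this kind of assay: it turns two-channel time-lapse stacks into
classified calcium responses, bead image pairs into substrate
displacement/strain maps, and cohorts of classified cells into exact
statistical comparisons between conditions.

## What it computes

**Response classification.** After background subtraction, the cell is
split into three bands of equal extent along the probe→centroid axis
(*closer*, *middle*, *farther*). Each band's YPet/ECFP ratio time course
gives a baseline and a stimulated relative increase
δ = (peak − baseline)/baseline. The response is

- **none** if max(δ) ≤ 0.10 (all bands within 10% of baseline),
- **global** if δ_farther ≥ 0.5 · δ_closer ("at least half"),
- **local** otherwise.

**Substrate mechanics.** Fiducial beads are tracked between a reference
and a displaced frame by Gaussian-weighted normalized cross-correlation
with sub-pixel refinement, interpolated onto a regular grid, and
differentiated with 2-point boundary / 3-point interior finite
differences to give the normal strains E_x = ∂u_x/∂x, E_y = ∂u_y/∂y and
the total strain E = √(E_x² + E_y²).

**Cohort statistics.** Class counts (n_g, n_l, n_n) per condition give
multinomial estimates p̂_k = n_k/N with sd √(p̂_k(1−p̂_k)/N); each
treatment is compared against the control with an exact
(Freeman–Halton) contingency-table test on the 2×3 table of counts,
significant at p < 0.05.

A synthetic-data module generates every input the pipeline consumes —
probe vibration traces, substrate fields with bead image pairs, and
two-channel FRET movies with known ground-truth class — so the full
chain is testable without microscopy data.

## Worked example

Simulate a 30-cell control cohort (80% global / 20% local ground truth),
analyze it, and summarize the substrate deformation:

```r
library(mechfret)

cfg <- pipeline_config(out_dir = tempfile("run"), seed = 1, n_cells = 30,
                       probabilities = c(global = 0.8, local = 0.2, none = 0))
cmd_simulate(cfg)            # writes movies, bead pair, trace, manifest
res <- cmd_analyze(cfg)      # per-cell classification + cohort report
res$report
```

```
#> cohort_report
#>  condition  N n_global n_local n_none p_global p_local p_none sd_global  sd_local sd_none
#>    control 30       24       6      0      0.8     0.2      0 0.0730297 0.0730297       0
```

All 30 phantoms are classified; at seed 1 the 24/6/0 split estimates
p̂_g = 0.80 ± 0.07, matching the generating probabilities. The substrate
branch recovers the imposed deformation field:

```r
s <- cmd_strain(cfg)
s$displacement$max_displacement_um
#> [1] 12.97879      # imposed peak: 13.5 um (recovered within ~4%)
s$strain$max_strain
#> [1] 0.2806577     # ~30% peak strain on the spline-regularized field
```

Classifying a single cell directly:

```r
cell  <- cell_phantom()                       # 125-um disc, probe 13 um away
movie <- generate_fret_movie(cell, response_model("local"), seed = 2)
run_cell(movie, cell$mask, cell$probe_position)
#> response_record: class = local
#>   baseline (closer/middle/farther): 1.204 / 1.2 / 1.202
#>   delta    (closer/middle/farther): 0.3688 / 0.07841 / 0.01691
```

The closer band rises 37% over baseline while the farther band rises
under 2% — below half of the closer band's rise — so the cell is a
local responder.

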