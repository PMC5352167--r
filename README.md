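# gridsuff

Grid-level sampling sufficiency of species inventories.

Quadrat-based plant surveys never cover a landscape evenly: terrain and
infrastructure concentrate effort, so the species list of some grid cells is
nearly complete while others are badly under-sampled. `gridsuff` takes
point-located quadrat occurrence records, aggregates them onto nested
latitude–longitude fishnets (e.g. 1° cells nested four-to-one in 2° cells),
and asks of every cell: *how complete is the inventory here, and where should
the next field campaign go?*

It is written for biodiversity informaticians and field ecologists curating
large quadrat databases, and ships a synthetic landscape-and-survey generator
with known ground truth so the whole pipeline is testable without any
proprietary field data.

## Method

Per cell, a sample-based species-accumulation curve (mean over seeded random
quadrat orderings) is fitted with the Clench model

    S(x) = a·x / (1 + b·x)

by damped Gauss–Newton nonlinear least squares: `a` is the initial
accumulation rate, `b` the saturation parameter, and `a/b` the predicted
asymptotic richness. Sampling sufficiency is the ratio `S_obs / (a/b)`,
classified against thresholds 60–80% (a cell is sufficient at `q` when the
ratio ≥ `q`). The theoretical effort to record a fraction `q` of the
predicted list is

    n_q = q / (b·(1 − q)),

which satisfies `S(n_q) = q·(a/b)` exactly. Cells with fewer than 5 quadrats
are excluded; cells with under 5% vegetated area can be excused from the
insufficiency count (two reporting modes). Under-sampled cells are ranked for
resurvey by a 50/50-weighted sum of two min–max-normalized criteria
(0–100 scale, bounds taken over the under-sampled cohort): number of
vegetation types and vegetation area.

## Worked example

The `analysis/` scripts run the reference workflow end to end:

```sh
Rscript analysis/01_simulate.R      # synthetic survey with ground truth
Rscript analysis/02_pipeline.R      # grid -> fit -> classify -> prioritize
Rscript analysis/03_recovery.R      # effort vs completeness experiment
Rscript analysis/04_scale_effect.R  # 1-degree vs 2-degree sufficiency
```

Output of steps 1–2 (64 one-degree cells, 16 two-degree cells, ~2,800
quadrats; all tables under `results/pipeline/`):

```
Simulated 33687 occurrence records in 2810 quadrats over 64 cells
True per-cell richness: 57-670 species; 13 remote cells surveyed at 40% effort
1-degree grid: 64 cells, 64 fitted, median r2 = 0.990, mean ratio = 0.802
2-degree grid: 16 cells, 16 fitted, median r2 = 0.988, mean ratio = 0.835

Threshold summary (sufficient cells, excluding / including mode):
  1 deg @ 60%: 63 (98.4%) / 63 (98.4%) of 64
  1 deg @ 65%: 60 (93.8%) / 61 (95.3%) of 64
  1 deg @ 70%: 58 (90.6%) / 59 (92.2%) of 64
  1 deg @ 75%: 48 (75.0%) / 50 (78.1%) of 64
  1 deg @ 80%: 31 (48.4%) / 33 (51.6%) of 64
  2 deg @ 60%: 16 (100.0%) / 16 (100.0%) of 16
  ...
6 under-sampled 1-degree cells ranked for resurvey (results/pipeline/priority.csv)
```

Reading: every cell's accumulation curve fits the Clench model tightly
(median r² ≈ 0.99). At the 70% threshold, 58 of 64 one-degree cells are
sufficiently sampled by ratio alone (90.6%), one more when low-vegetation
cells are excused; all 16 two-degree cells are sufficient — sufficiency is
strongly scale-dependent, because pooling four cells multiplies effort while
overlapping species pools grow sublinearly. The six insufficient 1° cells
(the remote, effort-starved ones) come out ranked by the weighted
heterogeneity/area score for resurvey planning.

Programmatic use mirrors the scripts:

```r
library(gridsuff)
res <- run_pipeline(pipeline_config(
  occurrences = "occurrences.csv",   # quadrat_id, lon, lat, species
  veg_table   = "veg_table.csv",     # cell_id, veg_fraction, veg_type_count
  resolutions = c(1, 2), global_seed = 1, out_dir = "out"))
res$summaries          # threshold ladder, both reporting modes
head(res$priority)     # ranked under-sampled cells
```

See `vignettes/sampling-sufficiency.Rmd` for the model, the numerical
choices, and what the synthetic generator does and does not emulate.

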