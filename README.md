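# camtrapnp

Temporal and spatio-temporal niche partitioning among sympatric species
from camera-trap detection records.

Whether two nocturnal carnivores actually avoid each other depends on the
time scale you look at: their diel activity curves can overlap almost
completely while one species still delays passing a camera for hours after
the other. `camtrapnp` implements, behind one data model, the four
analyses used to probe this across scales, for anyone working with
(site, species, date, time) detection tables:

1. **Activity overlap** — von Mises circular kernel density estimates per
   species and the coefficient of overlap
   $\hat\Delta = \int_0^{2\pi}\min\{\hat f_a(t),\hat f_b(t)\}\,dt$,
   estimated by $\hat\Delta_1$ (grid integration) or
   $\hat\Delta_4 = \tfrac12\big[\overline{\min(\hat f_b/\hat f_a,1)}\big|_{t_a}
   + \overline{\min(\hat f_a/\hat f_b,1)}\big|_{t_b}\big]$
   (preferred when both samples exceed 75), with smoothed-bootstrap
   confidence intervals and a low/moderate/high classification at
   0.5/0.75.
2. **Probabilistic nightly co-occurrence** — the number of site-nights
   both species are detected, against the exact hypergeometric law of
   independent placement (expected count $N_1N_2/N$, inclusive tail
   probabilities $P_{lt}$, $P_{gt}$).
3. **Checkerboard C-score** — checkerboard units $(r_1-S)(r_2-S)$ of the
   night matrix against a row-shuffle null model (row totals fixed),
   summarised as a standardized effect size (negative SES = more shared
   nights than chance) and a rank p-value.
4. **Time-to-encounter MRPP** — per ordered pair, the median waiting time
   from each detection of one species to the next detection of the other
   at the same camera, against random permutations of whole site histories
   within survey blocks; small p = segregation, large p = aggregation.
   A 15-h variant (`NOCTURNAL_CUTOFF_HOURS`) confines the test to the
   nocturnal window where fine-scale avoidance is visible.

Shared plumbing includes a 30-min independence filter, an internal NOAA
solar calculator (with override table) defining nights as sunset − 60 min
to sunrise + 60 min, a Mantel-correlogram spatial-autocorrelation check,
and a synthetic survey generator with exact ground truth (`true_overlap()`
by numerical integration, known presence odds ratios and avoidance
parameters) used to validate every stage.

## Worked example

Simulate the default three-species scenario (18 cameras, four staggered
May–October survey blocks over two seasons) and run the whole pipeline:

```r
library(camtrapnp)

sim <- simulate_detections(default_scenario(seed = 42))
table(sim$records$species)
#>      marten raccoon_dog     red_fox
#>         291         712         780

cfg <- analysis_config(species = c("red_fox", "raccoon_dog", "marten"),
                       n_boot = 1000, n_sim = 500, n_perm = 500,
                       mantel_n_perm = 999, seed = 42)
res <- run_pipeline(sim$records, sim$sites, cfg)
res
#> camtrapnp pipeline result
#>   species: red_fox, raccoon_dog, marten
#>   records: 1783 (1707 after filtering), site-nights: 2509
#>
#> Summary table (+ overlap/aggregation side, - partitioning side):
#>       before       after overlap prob_cooccurrence c_score mrpp mrpp_cutoff
#>      red_fox raccoon_dog       +                 +       +    +
#>  raccoon_dog     red_fox       +                 +       +    +
#>      red_fox      marten       +
#>       marten     red_fox       +
#>  raccoon_dog      marten       +
#>       marten raccoon_dog       +
```

Reading the table: every pair overlaps strongly in diel activity (`+` in
the overlap column), but only the red fox–raccoon dog pair also shares
*nights* more often than chance (probabilistic co-occurrence `+`, C-score
`+`) and encounters each other faster than random site assignment would
allow (MRPP `+`). Stage detail lives in the bundle:

```r
res$overlap[, c("species_a", "species_b", "n1", "n2", "delta",
                "ci_low", "ci_high", "class")]
#>     species_a   species_b  n1  n2 delta ci_low ci_high class
#> 1     red_fox raccoon_dog 745 677 0.803  0.763   0.842  high
#> 2     red_fox      marten 745 285 0.895  0.853   0.934  high
#> 3 raccoon_dog      marten 677 285 0.772  0.714   0.825  high

sim$truth$overlap          # generator ground truth for comparison
#>     species_a   species_b delta_true
#> 1     red_fox raccoon_dog      0.784
#> 2     red_fox      marten      0.810
#> 3 raccoon_dog      marten      0.772
```

`write_results(res, "out/")` exports every stage as CSV plus a JSON
manifest; the same configuration and seed reproduce the files
byte-for-byte. See the vignette
(`vignettes/niche-partitioning.Rmd`) for the models, parameter meanings,
and the package's numerical and design choices.

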