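# chronocal

Distance-calibrated divergence-time placement of newly discovered taxa.

## The problem

When a new species is sequenced for a standard marker (e.g. mitochondrial
16S), it is usually absent from published fossil-calibrated chronograms, so
its divergence time cannot be read off any tree. If its congeners *are* on
such a chronogram, a simple calibration gets around this: under an
approximately clock-like marker, the uncorrected p-distance between two
species grows with the age of their most recent common ancestor. Fitting

```
y = b * x + a
```

where `x` is the percent p-distance of a species pair and `y` its divergence
time in millions of years (My) on the published chronogram, turns the
chronogram into a local molecular clock. The new taxon's smallest genetic
distance to its relatives, inserted into the fitted line, gives a minimum
estimate of its divergence time — for example, a calibration line
`y = 2.74x + 2.17` evaluated at the midpoint of a 2.2–2.9% distance range
(2.55%) yields approximately 9.2 My, placing the split well before the
Quaternary (2.58 My).

`chronocal` implements this workflow end to end for R users:

* **p-distances** — uncorrected p-distance matrices from aligned FASTA under
  pairwise deletion (any column where either symbol is not an unambiguous
  A/C/G/T is skipped for that pair), with per-pair comparable-site counts
  and barcoding-style species-pair percent-range tables.
* **chronogram ages** — Newick parsing, ultrametricity checking, and
  MRCA-age extraction for tip or species pairs (`ape` underneath).
* **calibration** — least-squares fits of time on percent distance, both
  unconstrained and constrained through the origin (with the uncentered R²
  conventional for no-intercept regression), and time prediction with
  regression prediction intervals or a fixed ± half-width.
* **placement** — a pipeline from alignment + species map + chronogram +
  focal species to a placement report (nearest relative, distance range,
  predicted time with uncertainty, Quaternary flag), refusing to calibrate
  on any pair involving the focal taxon.
* **simulation** — Yule chronograms and strict-clock Jukes–Cantor alignments
  with conspecific individuals, plus focal-holdout scenarios with a known
  true divergence time, used to validate every stage.

## Worked example

```r
library(chronocal)

# a synthetic study: 10 species, 2 individuals each, crown age 30 My,
# strict clock at 5e-4 substitutions/site/My, 2000 sites; one non-basal
# species is held out of the chronogram as the "new" taxon
sc  <- simulate_focal_holdout(seed = 42)
rep <- place_taxon(sc$alignment, sc$species_map, sc$chronogram, sc$focal)
rep
#> Placement report for 'sp10'
#>   nearest relative: sp01 (0.2-0.3%)
#>   distance used: 0.250% (mean of range)
#>   fit unconstrained: y = 10.263 x + 0.369, R^2 = 0.980, n = 36  [headline]
#>   fit through_origin: y = 10.407 x + 0.000, R^2 = 0.997, n = 36
#>   predicted divergence: 2.9 My (0.0-5.9; regression prediction interval, level 0.95)
#>   pre-dates Quaternary (2.58 My): no
#>   within-focal divergence: 0.2-0.2% (inside reference 0.2-0.9)
sc$true_time_my
#> [1] 2.388961
```

The fitted slope of ~10 My per percent matches the theoretical strict-clock
value `1 / (200 * mu)` for `mu = 5e-4`, and the predicted 2.9 My is close to
the known true divergence time of 2.4 My.

Published calibration lines can be used directly:

```r
fit <- calibration_fit(slope = 2.74, intercept = 2.17)
predict_time(fit, distance_range_summary(2.2, 2.9),
             interval = "fixed", halfwidth = 4)
#> Predicted divergence time: 9.2 My (5.2-13.2 My; fixed half-width 4 My)
```

## Command line

A thin launcher over the same functions is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "chronocal.R", package = "chronocal"))')
Rscript $CLI simulate --species 10 --individuals 2 --crown-age 30 \
        --mu 5e-4 --sites 2000 --seed 42 --out-dir scenario/
Rscript $CLI place scenario/alignment.fasta \
        --species-map scenario/species_map.tsv \
        --chronogram scenario/chronogram.nwk --focal sp10 --out report.json
```

Subcommands: `distances`, `pairtimes`, `calibrate`, `place`, `simulate`.
All outputs are deterministic for a fixed `--seed`.

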