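# mpscreen

Semi-automated fluorescence screening of microplastic (MP) particles on
filter membranes.

## What it does, and for whom

Monitoring MP in seafood needs methods faster than particle-by-particle
infrared or Raman identification. One practical route is to digest the
tissue, filter the digestate, stain the filter with Nile red and image
it with fluorescence microscopy: stained polymers light up brightly with
a red-dominated emission, while most matrix particles of natural origin
(PNO — fishbone, chitin, shell, cellulose) stay dim or off-colour. The
catch is that naive counting of fluorescent objects badly overestimates
MP, and manual image editing makes results operator-dependent.

`mpscreen` is for analysts running such screens. It converts a
calibrated RGB filter scan into a per-particle table and blank-corrected
MP counts and mass estimates, with every step deterministic and
recorded:

* **Segmentation** — global Otsu brightness thresholding (brightness =
  max(R,G,B)), optional morphological opening, 8-connected labelling
  with a minimum-area filter.
* **Morphometry** — area, Crofton perimeter, maximum Feret diameter,
  fitted-ellipse axes, aspect ratio, circularity `4πA/P²`.
* **Fluorescence** — total particle brightness (TPB = mean over particle
  pixels of max(R,G,B)) and RGB colour fractions.
* **Classification** — shape (fragment / spheroid / fibre) from aspect
  ratio and circularity; fluorescence group (weak / medium / bright)
  from TPB; a particle is **MP-suspect** when TPB ≥ 45 and its red
  fraction lies in [0.34, 0.80] (all cuts configurable and
  serialisable).
* **Quantification** — six Feret size classes (5–10, 10–50, 50–100,
  100–500, 500–1000, 1000–5000 µm); volumes from sphere / cuboid /
  cylinder models; mass = volume × density × 10⁻⁶ µg.
* **Blank correction** — per category (size × shape × fluorescence),
  the procedural blanks give LOQ = mean + 10 × SD; results above the
  LOQ are blank-mean-subtracted, results below are censored to zero.
* **Synthetic fixtures** — a seeded generator renders ground-truthed
  stained-filter images (bright shapes on noisy dim background), so the
  whole pipeline is testable offline.

Statistics used in method validation are included: RSD, spike
expectations, recovery, MP fractions, filter-membrane areas, and
confusion-matrix error reports (α = PNO falsely flagged, β = MP missed).

## Worked example

Simulate a spiked filter (25 bright polystyrene-like particles), three
clean procedural blanks, and run the corrected series:

```r
library(mpscreen)

pop <- samplePopulation(list(particleClassSpec(
  "PS", "MP", 25, c(fragment = 0.4, spheroid = 0.6, fibre = 0),
  size_median_um = 60, size_log_sd = 0.4,
  tpb_mean = 88, tpb_sd = 18, red_mean = 0.52, red_sd = 0.05)), seed = 8)
out <- renderFilterImage(pop, renderSpec(width_px = 512, height_px = 512),
                         seed = 8)
blanks <- lapply(31:33, function(s)
  renderFilterImage(pop[0, ], renderSpec(width_px = 256, height_px = 256),
                    seed = s)$image)
rep <- runSeries(seriesConfig(samples = list(spiked = out$image),
                              blanks = blanks))
rep$samples$spiked$summary
#> SampleSummary 'spiked' (blank-corrected)
#>   MP-suspect: 25 particles, 6.553 ug (raw); 25 particles, 6.553 ug (corrected)
rep$samples$spiked$log
#> $threshold_used   49.30664
#> $n_components_raw 25
#> $n_mp_suspect     25
```

All 25 rendered particles are detected (the automatic threshold, 49.3,
sits between the background at ~8 and the particles at ~88), all are
flagged MP-suspect, and — the blanks being clean — the corrected totals
equal the raw ones. The per-particle table holds the audit trail:

```r
head(rep$samples$spiked$particles[, c("particle_id", "feret_max_um",
  "tpb", "red_fraction", "shape_class", "size_class", "mp_suspect")])
#>   particle_id feret_max_um      tpb red_fraction shape_class size_class mp_suspect
#> 1       p0001     72.11103 95.49456    0.5104788    fragment     50-100       TRUE
#> 2       p0002     65.00000 77.48253    0.5835833    spheroid     50-100       TRUE
#> 3       p0003     61.03278 92.98957    0.5637829    fragment     50-100       TRUE
#> ...
```

`writeReports(rep, "out/")` writes per-particle CSVs, per-sample
CSV/JSON summaries and a series-level JSON with the LOQ table,
censoring flags and a configuration hash. A thin command-line wrapper
with `analyze`, `series`, `simulate` and `report` subcommands lives in
`inst/cli/mpscreen.R`.

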